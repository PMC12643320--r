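#' Derive a component seed from a master seed
#'
#' Every randomized routine in the package draws its seed deterministically
#' from a master seed and a stable component label, so that a single
#' `--seed` reproduces an entire analysis while independent components still
#' get decorrelated streams.
#'
#' @param master integer master seed.
#' @param label character label naming the component (e.g. `"walk_s03"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master %% 2147483647)
  for (k in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_matrix <- function() matrix(numeric(0), 0, 0)
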