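# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent child seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Map perception labels to the classifier's +/-1 coding; "pain" is the
# positive class so positive weights mean higher activity on painful trials.
to_pm1 <- function(labels) {
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(-1, 1))) stop("numeric labels must be coded -1/+1")
    return(as.integer(labels))
  }
  x <- as.character(labels)
  ok <- x %in% c("pain", "no_pain")
  if (!all(ok)) stop("labels must be 'pain'/'no_pain' (or -1/+1)")
  ifelse(x == "pain", 1L, -1L)
}

pm1_to_label <- function(y) {
  out <- rep(NA_character_, length(y))
  out[!is.na(y) & y > 0] <- "pain"
  out[!is.na(y) & y < 0] <- "no_pain"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
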