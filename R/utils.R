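# internal helpers shared across modules

# evaluate expr under a fixed RNG seed without disturbing the caller's RNG;
# seed = NULL means "use the current RNG stream"
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(expr))
}

.assertCounts <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(name, " must be a numeric vector without NA", call. = FALSE)
  }
  if (any(x < 0) || any(x != floor(x))) {
    stop(name, " must contain non-negative integers", call. = FALSE)
  }
  invisible(x)
}

.assertProb <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(name, " must be a single probability in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# coerce a count container (matrix / data.frame / SummarizedExperiment) to a
# features-by-samples numeric matrix with rownames
.countMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, 1L)
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)) && nrow(x) > 0) {
    rownames(x) <- paste0("f", seq_len(nrow(x)))
  }
  storage.mode(x) <- "double"
  x
}

# short fingerprint of a configuration string, for provenance headers
.configHash <- function(cfg) {
  v <- utf8ToInt(paste(cfg, collapse = "|"))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2^28
  sprintf("%07x", h)
}

.provenanceHeader <- function(seed = NA, cfg = "") {
  c(
    paste0("# bzinbcor ", as.character(utils::packageVersion("bzinbcor"))),
    paste0("# config: ", .configHash(cfg)),
    paste0("# seed: ", seed)
  )
}
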