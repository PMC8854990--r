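# internal numerical helpers

.relu <- function(x) (x > 0) * x
.reluGrad <- function(a) (a > 0) * 1

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.clip <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# derived seeds must stay valid 32-bit integers
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.checkFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# one-hot encode site labels against a fixed level set
.siteOnehot <- function(site, levels) {
  v <- numeric(length(levels))
  i <- match(site, levels)
  if (is.na(i)) stop(sprintf("unknown site label '%s'", site), call. = FALSE)
  v[i] <- 1
  v
}
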