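#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so generators compose without clobbering global RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Least-squares slope (and R^2) of y on x, vectorised over the columns of a
# matrix `Y`; x is the common abscissa. Rows with non-finite y are not
# tolerated here -- callers mask beforehand.
.ls_slope <- function(x, Y) {
  Y <- as.matrix(Y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(Y, 2L, colMeans(Y))
  slope <- colSums(xc * yc) / sxx
  ss_tot <- colSums(yc^2)
  ss_res <- ss_tot - slope^2 * sxx
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  list(slope = as.numeric(slope), r2 = as.numeric(r2))
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
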