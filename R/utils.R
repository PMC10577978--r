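# Internal helpers shared across modules.

# Ratio phi(z)/Phi(z), stable far into the left tail.
inv_mills <- function(z) {
  exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
}

# Draw from Normal(mean, sd) truncated above at `upper` by inverse-CDF.
# Stable when the truncation point is deep in the lower tail: work with
# log CDF values so Phi(upper) ~ 0 does not underflow to a degenerate draw.
rtruncnorm_upper <- function(n, mean, sd, upper) {
  log_p_upper <- pnorm((upper - mean) / sd, log.p = TRUE)
  u <- runif(n)
  # quantile at u * Phi(upper): log scale addition
  q <- qnorm(log(u) + log_p_upper, log.p = TRUE)
  # guard against -Inf from extreme underflow
  q <- pmax(q, -38)
  mean + sd * q
}

# Quantile scores: number of cutpoints strictly below each value
# (ties at a cutpoint fall to the lower score).
score_from_cutpoints <- function(x, cutpoints) {
  findInterval(x, sort(cutpoints), left.open = TRUE)
}

# Drop covariate columns that are constant on the analysis rows (e.g. a
# factor level absent from a subsample), which would make the information
# matrix singular. Columns named in `protect` are never dropped.
drop_constant_columns <- function(X, protect = "(Intercept)") {
  keep <- vapply(seq_len(ncol(X)), function(j) {
    colnames(X)[j] %in% protect || length(unique(X[, j])) > 1
  }, logical(1))
  X[, keep, drop = FALSE]
}

# Drop columns that are exactly or numerically aliased by earlier columns
# (rank deficiency, e.g. tract-level covariates spanning few tracts).
# Protected columns are kept up front so aliasing resolves against them last.
drop_aliased_columns <- function(X, protect = "(Intercept)") {
  ord <- c(which(colnames(X) %in% protect),
           which(!colnames(X) %in% protect))
  Xo <- X[, ord, drop = FALSE]
  q <- qr(Xo)
  if (q$rank == ncol(Xo)) return(X)
  keep_nm <- colnames(Xo)[q$pivot[seq_len(q$rank)]]
  lost_protected <- setdiff(intersect(protect, colnames(X)), keep_nm)
  if (length(lost_protected) > 0) {
    stop_wellmix(paste0("exposure column(s) aliased by covariates: ",
                        paste(lost_protected, collapse = ", ")), "rank_error")
  }
  X[, colnames(X) %in% keep_nm, drop = FALSE]
}

stop_wellmix <- function(msg, class) {
  rlang::abort(msg, class = paste0("wellmix_", class))
}
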