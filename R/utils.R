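# internal helpers

# log(sum(exp(x))) grouped by an integer/factor index, numerically stable
groupedLogSumExp <- function(x, group) {
  g <- as.integer(factor(group, levels = unique(group)))
  mx <- tapply(x, g, max)
  s <- rowsum(exp(x - mx[g]), g)
  as.numeric(log(s) + mx)
}

# subtract the group mean from each column (matrix version of within-set centering)
centerWithin <- function(X, group) {
  g <- as.integer(factor(group, levels = unique(group)))
  n <- tabulate(g)
  X - rowsum(X, g)[g, , drop = FALSE] / n[g]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# truncated-normal draws via inverse-cdf; used for diagnosis ages
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}
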