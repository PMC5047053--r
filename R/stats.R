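#' Group summary (mean, SD, n)
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled two-sample t test from group summaries
#'
#' Equal-variance Student's t computed from (mean, SD, n) summaries, the
#' form reconstructable from published group statistics:
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, a 95% CI on the
#' mean difference and a two-sided p.
#'
#' @param a,b `group_summary` objects (or lists with mean/sd/n).
#' @param conf.level confidence level for the CI (default 0.95).
#' @return an object of class `htest` with `statistic` (t), `parameter`
#'   (df), `conf.int`, `estimate` (mean difference) and `p.value`.
#' @examples
#' pooled_t_test(group_summary(86.38, 18.94, 8),
#'               group_summary(82.86, 10.03, 7))
#' @export
pooled_t_test <- function(a, b, conf.level = 0.95) {
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- a$mean - b$mean
  if (sp2 == 0) {
    if (diff != 0) stop("zero pooled variance with unequal means")
    tstat <- 0; se <- 0
  } else {
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    tstat <- diff / se
  }
  tcrit <- stats::qt(1 - (1 - conf.level) / 2, df)
  ci <- diff + c(-1, 1) * tcrit * se
  attr(ci, "conf.level") <- conf.level
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(tstat), df),
                 conf.int = ci, estimate = c(`mean difference` = diff),
                 method = "Pooled two-sample t test from summaries",
                 data.name = "a vs b"),
            class = "htest")
}

#' Mann-Whitney U test
#'
#' Rank-sum U with mid-rank ties. The reported statistic is
#' `min(U_x, U_y)`, the convention of most clinical reports. The p value
#' uses exact enumeration over all group assignments when
#' `min(n) <= exact_limit`, otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y numeric (possibly ordinal) samples.
#' @param exact_limit largest `min(n)` for which the exact enumeration is
#'   used (default 8).
#' @return `htest` with `statistic` (U = min of the two orientations) and
#'   `p.value`; `estimate` carries `U_x` (pairs with x > y counting ties
#'   as 1/2).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 8) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  ux <- rx - nx * (nx + 1) / 2          # pairs with x > y (+ half-ties)
  uy <- nx * ny - ux
  u <- min(ux, uy)
  if (min(nx, ny) <= exact_limit) {
    p <- u_exact_p(r, nx, ny, u)
  } else {
    # normal approximation with tie correction, continuity-corrected
    nt <- nx + ny
    ties <- table(c(x, y))
    tiecor <- sum(ties^3 - ties) / (nt * (nt - 1))
    sdu <- sqrt(nx * ny / 12 * (nt + 1 - tiecor))
    mu <- nx * ny / 2
    z <- (u - mu + 0.5) / sdu
    p <- min(1, 2 * stats::pnorm(z))
  }
  structure(list(statistic = c(U = u), p.value = p,
                 estimate = c(U_x = ux),
                 method = sprintf(
                   "Mann-Whitney U (min of the two orientations; %s p)",
                   if (min(nx, ny) <= exact_limit) "exact" else
                     "normal-approximation"),
                 data.name = "x vs y"),
            class = "htest")
}

# exact two-sided p by enumerating all choose(nx+ny, nx) assignments of
# the observed (tied) ranks; two-sided p doubles the smaller tail.
u_exact_p <- function(r, nx, ny, u_obs) {
  nt <- nx + ny
  idx <- utils::combn(nt, min(nx, ny))
  n1 <- min(nx, ny)
  rs <- colSums(matrix(r[idx], nrow = n1))
  u1 <- rs - n1 * (n1 + 1) / 2
  us <- pmin(u1, n1 * (nt - n1) - u1)
  mean(us <= u_obs + 1e-9)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement over the union of both raters'
#' categories.
#'
#' @param r1,r2 equal-length categorical rating vectors.
#' @return kappa (scalar).
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rating vectors must have equal length")
  lev <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = lev); f2 <- factor(r2, levels = lev)
  tab <- table(f1, f2) / length(r1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps * 8)
    stop("kappa undefined: both raters constant and identical")
  (po - pe) / (1 - pe)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS statistic against a normal distribution with the
#' sample's own mean and SD (Lilliefors-type plug-in); the p value is
#' obtained by Monte-Carlo simulation under the same plug-in procedure,
#' since the classical KS null distribution does not apply when
#' parameters are estimated.
#'
#' @param x numeric sample, `n >= 4`, non-constant.
#' @param nsim number of null simulations for p (default 2000).
#' @return `htest` with `statistic` (D) and simulated `p.value`.
#' @export
ks_normality <- function(x, nsim = 2000) {
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0) stop("constant sample")
  D <- lilliefors_stat(x)
  sims <- vapply(seq_len(nsim),
                 function(i) lilliefors_stat(stats::rnorm(n)), numeric(1))
  p <- (sum(sims >= D) + 1) / (nsim + 1)
  structure(list(statistic = c(D = D), p.value = p,
                 method = "KS normality test, plug-in mean/SD, simulated p",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  cdf <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n))
}

#' Per-group sample size for a two-sample t test at effect size d
#'
#' Smallest integer n per group whose two-sided two-sample t power
#' reaches the target at the given standardized effect size.
#'
#' @param d Cohen's d (> 0).
#' @param alpha two-tailed significance level (default 0.05).
#' @param power target power (default 0.8).
#' @return integer n per group.
#' @examples
#' sample_size_cohens_d(1.2)   # 12
#' @export
sample_size_cohens_d <- function(d, alpha = 0.05, power = 0.8) {
  if (d <= 0) stop("d must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  n <- 2L
  repeat {
    pw <- stats::power.t.test(n = n, delta = d, sd = 1, sig.level = alpha,
                              type = "two.sample",
                              alternative = "two.sided")$power
    if (pw >= power) return(n)
    n <- n + 1L
    if (n > 1e6) stop("no attainable n below 1e6")
  }
}

#' Radiographic fracture-healing score
#'
#' Three-category ordinal score: periosteal reaction 0-3 (none, mild
#' <50%, moderate >50%, full across the defect), quality of bone union
#' 0-3 (nonunion, mild bridge, moderate bridge, full bridge), remodeling
#' 0-2 (none, mild, full cortex). The total is their sum; a completely
#' healed fracture scores 8.
#'
#' @param periosteal integer(s) in 0-3.
#' @param union integer(s) in 0-3.
#' @param remodeling integer(s) in 0-2.
#' @return data frame of class `radiograph_score` with the three
#'   categories and `total`.
#' @export
score_radiograph <- function(periosteal, union, remodeling) {
  chk <- function(v, hi, nm) {
    if (any(v != round(v)) || any(v < 0) || any(v > hi))
      stop(nm, " must be an integer in 0..", hi)
  }
  chk(periosteal, 3, "periosteal"); chk(union, 3, "union")
  chk(remodeling, 2, "remodeling")
  out <- data.frame(periosteal = as.integer(periosteal),
                    union = as.integer(union),
                    remodeling = as.integer(remodeling))
  out$total <- out$periosteal + out$union + out$remodeling
  class(out) <- c("radiograph_score", "data.frame")
  out
}
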