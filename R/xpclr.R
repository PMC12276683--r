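#' Selection-parameter grid for the composite-likelihood sweep scan
#'
#' The scan maximizes the composite likelihood over a grid of selection
#' strengths that must contain 0 (the neutral model, where the sweep
#' likelihood reduces exactly to the drift null).
#'
#' @param s_values grid of selection parameters; default `{0}` plus 15
#'   log-spaced values between 1e-5 and 1e-1.
#' @param recomb_cM_per_Mb recombination rate used for the distance decay
#'   (default 1 cM/Mb).
#' @return a `sweep_grid` list.
#' @export
sweep_grid <- function(s_values = c(0, 10^seq(-5, -1, length.out = 15)),
                       recomb_cM_per_Mb = 1) {
  if (!length(s_values) || !any(s_values == 0)) {
    stop("the selection grid must contain 0")
  }
  structure(list(s_values = sort(unique(s_values)),
                 recomb_cM_per_Mb = recomb_cM_per_Mb),
            class = "sweep_grid")
}

#' Method-of-moments drift variance
#'
#' Genome-wide estimate of the drift variance scale `omega`: the mean over
#' sites of `(p_obj - p_ref)^2 / (p_ref (1 - p_ref))`, with frequencies
#' clamped to \[0.01, 0.99\]. Requires at least 100 sites.
#'
#' @param p_ref,p_obj allele frequencies in the reference and object
#'   populations.
#' @return omega estimate (a single non-negative number).
#' @export
estimate_omega <- function(p_ref, p_obj) {
  ok <- !is.na(p_ref) & !is.na(p_obj)
  p_ref <- pmin(pmax(p_ref[ok], 0.01), 0.99)
  p_obj <- pmin(pmax(p_obj[ok], 0.01), 0.99)
  if (length(p_ref) < 100) stop("estimate_omega needs at least 100 polymorphic sites")
  mean((p_obj - p_ref)^2 / (p_ref * (1 - p_ref)))
}

# Censored-normal density evaluated on the fixed quadrature: returns the
# per-site likelihood sum(weight * density * binom) + boundary masses.
# mu, sd: per-site vectors; B: n_quad x S binomial matrix; k, n: counts.
censored_normal_lik <- function(mu, sd, B, k, n, x, w) {
  D <- stats::dnorm(outer(x, mu, "-") / rep(sd, each = length(x))) /
    rep(sd, each = length(x))
  lik <- colSums(D * B) * w
  m0 <- stats::pnorm(0, mu, sd)
  m1 <- 1 - stats::pnorm(1, mu, sd)
  lik + m0 * as.numeric(k == 0) + m1 * as.numeric(k == n)
}

#' Composite-likelihood sweep score for one window
#'
#' Drift null: the object-population frequency at each site is a censored
#' normal around the reference frequency with variance
#' `omega * p (1 - p)`; the site likelihood integrates the binomial count
#' likelihood over that density (fixed 512-point quadrature plus boundary
#' masses). Sweep alternative at strength `s`: with probability
#' `c = 1 - exp(-r d / s)` (distance `d` from the window center, `r` in
#' Morgans/bp) a site escapes the sweep and follows the null; otherwise it
#' hitchhikes, which pulls the frequency distribution to a two-component
#' mixture with mass `p` centered at `1 - c (1 - p)` and mass `1 - p`
#' centered at `c p`, each with variance `c omega p (1 - p)` (floored at
#' 1e-6). The score is `2 max_s sum_sites (L(s) - L0)`, floored at 0; with
#' `s = 0`, `c = 1` and the alternative equals the null exactly.
#'
#' @param k,n alt-allele counts and allele totals per site in the object
#'   population.
#' @param p_ref reference-population frequencies per site (clamped to
#'   \[0.01, 0.99\]).
#' @param pos site positions (bp).
#' @param center window center (bp).
#' @param omega drift variance from [estimate_omega()].
#' @param grid a [sweep_grid()].
#' @param n_quad number of quadrature points.
#' @return list: `clr` (the score), `s_hat` (maximizing grid value),
#'   `loglik` (per-grid composite log-likelihood differences), `n_sites`.
#' @export
xpclr_window <- function(k, n, p_ref, pos, center, omega, grid = sweep_grid(),
                         n_quad = 512) {
  usable <- !is.na(k) & !is.na(p_ref) & n > 0
  k <- k[usable]; n <- n[usable]; pos <- pos[usable]
  p <- pmin(pmax(p_ref[usable], 0.01), 0.99)
  if (!length(k)) return(list(clr = NA_real_, s_hat = NA_real_,
                              loglik = NULL, n_sites = 0L))
  x <- (seq_len(n_quad) - 0.5) / n_quad
  w <- 1 / n_quad
  S <- length(k)
  B <- matrix(stats::dbinom(rep(k, each = n_quad), rep(n, each = n_quad),
                            rep(x, S)), n_quad, S)
  q <- 1 - p
  var0 <- pmax(omega * p * q, 1e-6)
  L0 <- log(censored_normal_lik(p, sqrt(var0), B, k, n, x, w))
  r_m_per_bp <- grid$recomb_cM_per_Mb * 1e-8
  d <- abs(pos - center)
  diffs <- vapply(grid$s_values, function(s) {
    if (s == 0) return(0)
    cc <- 1 - exp(-r_m_per_bp * d / s)
    varS <- pmax(cc * omega * p * q, 1e-6)
    sdS <- sqrt(varS)
    lik <- p * censored_normal_lik(1 - cc * q, sdS, B, k, n, x, w) +
      q * censored_normal_lik(cc * p, sdS, B, k, n, x, w)
    sum(log(lik) - L0)
  }, numeric(1))
  best <- which.max(diffs)
  list(clr = max(0, 2 * diffs[best]), s_hat = grid$s_values[best],
       loglik = diffs, n_sites = S)
}

#' Windowed composite-likelihood sweep scan
#'
#' Computes per-site allele frequencies and counts for the object and
#' reference populations, estimates the drift variance genome-wide, and
#' scores every window with [xpclr_window()].
#'
#' @param vs a `VariantSet`.
#' @param popmap named population vector.
#' @param pop_obj population scanned for sweeps (e.g. the hybrid breed).
#' @param pop_ref contrast population.
#' @param windows data.frame from [make_windows()]; built from
#'   `chrom_lengths` when omitted.
#' @param chrom_lengths named lengths for the default tiling.
#' @param size,step window geometry.
#' @param grid a [sweep_grid()].
#' @param omega drift variance; estimated from the data when `NULL`.
#' @return data.frame of scored windows: `chrom`, `start`, `end`,
#'   `n_sites`, `score`, `s_hat`; attribute `omega`.
#' @export
xpclr_scan <- function(vs, popmap, pop_obj, pop_ref, windows = NULL,
                       chrom_lengths = NULL, size = 50000, step = 25000,
                       grid = sweep_grid(), omega = NULL) {
  if (is.null(windows)) {
    if (is.null(chrom_lengths)) stop("supply windows or chrom_lengths")
    windows <- make_windows(chrom_lengths, size, step)
  }
  so <- which(popmap[vs$samples] == pop_obj)
  sr <- which(popmap[vs$samples] == pop_ref)
  if (!length(so) || !length(sr)) stop("population label absent from cohort")
  g_o <- vs$geno[, so, drop = FALSE]
  g_r <- vs$geno[, sr, drop = FALSE]
  k_obj <- rowSums(g_o, na.rm = TRUE)
  n_obj <- 2 * rowSums(!is.na(g_o))
  p_ref <- rowSums(g_r, na.rm = TRUE) / pmax(2 * rowSums(!is.na(g_r)), 1)
  p_ref[rowSums(!is.na(g_r)) == 0] <- NA
  p_obj <- ifelse(n_obj > 0, k_obj / n_obj, NA)
  if (is.null(omega)) omega <- estimate_omega(p_ref, p_obj)

  res <- lapply(seq_len(nrow(windows)), function(i) {
    wrow <- windows[i, ]
    sel <- which(vs$sites$chrom == wrow$chrom & vs$sites$start >= wrow$start &
                   vs$sites$start < wrow$end)
    if (!length(sel)) return(NULL)
    xw <- xpclr_window(k_obj[sel], n_obj[sel], p_ref[sel],
                       vs$sites$start[sel], (wrow$start + wrow$end) / 2,
                       omega, grid)
    if (!xw$n_sites) return(NULL)
    data.frame(chrom = wrow$chrom, start = wrow$start, end = wrow$end,
               n_sites = xw$n_sites, score = xw$clr, s_hat = xw$s_hat)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = integer(), score = numeric(), s_hat = numeric())
  }
  attr(out, "omega") <- omega
  out
}
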