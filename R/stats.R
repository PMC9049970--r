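#' Fit the task-related-response mixed model
#'
#' Fits the response on the fixed-effects design with a random intercept
#' per observer and random slopes for the three task predictors
#' (`fMRI_TO`, `fMRI_BP`, `fMRI_ToT`).  With `random = NULL` the model
#' reduces to ordinary least squares on the fixed effects (the zero
#' random-effect-variance limit).
#'
#' @param design a `design_matrix` from [assemble_design()] (includes the
#'   intercept column).
#' @param response numeric vector or [sampled_signal()], one value per row.
#' @param observer factor/character of observer ids, one per row; required
#'   for the mixed fit.
#' @param random character vector of design columns given random slopes per
#'   observer (plus a random intercept), or NULL for the OLS limit.
#' @param reml logical, REML (default) or ML.
#' @return a `trr_fit` list: `coefficients`, `se`, `vcov`, `fitted`,
#'   `residuals`, `r_squared`, `n`, `p`, `model` (the underlying lm/lmer
#'   object), `singular` (TRUE when the random-effects covariance was
#'   singular and the fit was kept with variances at the boundary).
#' @export
fit_mixed_model <- function(design, response, observer = NULL,
                            random = c("fMRI_TO", "fMRI_BP", "fMRI_ToT"),
                            reml = TRUE) {
  X <- unclass(design)
  y <- if (inherits(response, "sampled_signal")) response$values else as.numeric(response)
  if (length(y) != nrow(X)) stop("response length must equal design rows")
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.y <- y
  fixed_terms <- paste(names(df)[names(df) != ".y"], collapse = " + ")
  singular <- FALSE
  if (is.null(random)) {
    fm <- stats::as.formula(paste(".y ~ 0 +", fixed_terms))
    mod <- stats::lm(fm, data = df)
    beta <- stats::coef(mod)
    V <- suppressWarnings(stats::vcov(mod))   # warns on exact fits
    se <- sqrt(diag(V))
    fitted <- stats::fitted(mod)
  } else {
    if (is.null(observer)) stop("observer ids are required for the mixed fit")
    if (length(unique(observer)) < 2) stop("need >= 2 observers for random effects")
    df$.obs <- factor(observer)
    re_cols <- make.names(random)
    if (!all(re_cols %in% names(df))) stop("random-effect columns not in design")
    fm <- stats::as.formula(paste(
      ".y ~ 0 +", fixed_terms,
      "+ (1 +", paste(re_cols, collapse = " + "), "| .obs)"))
    mod <- lme4::lmer(fm, data = df, REML = reml,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    singular <- lme4::isSingular(mod)
    beta <- lme4::fixef(mod)
    V <- as.matrix(stats::vcov(mod))
    se <- sqrt(diag(V))
    fitted <- stats::fitted(mod)
  }
  fitted <- unname(fitted)
  resid <- y - fitted
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, se = se, vcov = V, fitted = fitted,
                 residuals = resid,
                 r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
                 n = length(y), p = ncol(X), model = mod,
                 singular = singular),
            class = "trr_fit")
}

#' Random-effect estimates per observer
#' @param fit a `trr_fit` from a mixed fit.
#' @return data.frame of conditional modes (one row per observer).
#' @export
random_effects <- function(fit) {
  stopifnot(inherits(fit, "trr_fit"))
  if (!inherits(fit$model, "merMod")) stop("not a mixed fit")
  as.data.frame(lme4::ranef(fit$model)$.obs)
}

#' Wald F-test for linear combinations of fixed effects
#'
#' Tests H0: L beta = 0 with F = (L b)' (L V L')^-1 (L b) / q, where q is
#' the rank of L, and a residual-based denominator degrees of freedom
#' approximation df2 = n - p.
#'
#' @param fit a `trr_fit`.
#' @param L contrast matrix (rows = contrasts) or a single contrast vector,
#'   with columns matching the fixed coefficients.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
contrast_ftest <- function(fit, L) {
  stopifnot(inherits(fit, "trr_fit"))
  L <- rbind(L)
  if (ncol(L) != length(fit$coefficients))
    stop("contrast columns must match the coefficient count")
  if (all(L == 0)) stop("zero contrast matrix")
  qrt <- qr(t(L))
  q <- qrt$rank
  L <- L[sort(qrt$pivot[seq_len(q)]), , drop = FALSE]   # independent rows only
  Lb <- L %*% fit$coefficients
  M <- L %*% fit$vcov %*% t(L)
  Fstat <- as.numeric(t(Lb) %*% solve(M, Lb)) / q
  df2 <- fit$n - fit$p
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Named contrast row over design columns
#' @param design a `design_matrix` (or character vector of labels).
#' @param weights named numeric, e.g. `c("fMRI_TO:difficulty" = 1, ...)`.
#' @return numeric contrast vector aligned with the columns.
#' @export
contrast_row <- function(design, weights) {
  labels <- if (is.character(design)) design else colnames(design)
  v <- stats::setNames(numeric(length(labels)), labels)
  if (!all(names(weights) %in% labels))
    stop("unknown design columns: ",
         paste(setdiff(names(weights), labels), collapse = ", "))
  v[names(weights)] <- weights
  unname(v)
}

#' Exact p-value for a finite permutation sample
#'
#' p = (b + 1) / (m + 1), where b of m permutation statistics reach the
#' observed value; never 0, with floor 1/(m + 1).
#'
#' @param b exceedance count (0 <= b <= m).
#' @param m number of permutations (>= 1).
#' @return probability in (0, 1].
#' @export
exact_p <- function(b, m) {
  if (m < 1) stop("m must be >= 1")
  if (b < 0 || b > m) stop("b must lie in [0, m]")
  (b + 1) / (m + 1)
}

#' Two-group permutation test with exact-p correction
#'
#' Test statistic: difference of group means (group1 - group2).  Labels are
#' shuffled `m` times (or all distinct assignments are enumerated when
#' `exhaustive = TRUE` and feasible); b counts null statistics at or beyond
#' the observed one (ties count as exceeding, the conservative convention);
#' p = (b + 1)/(m + 1).
#'
#' @param values numeric per-trial values.
#' @param labels two-level grouping (logical, factor or character).
#' @param m number of random permutations.
#' @param tail "right" (group1 mean larger) or "left".
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all label assignments instead of sampling
#'   (feasible up to ~20 choose 10).
#' @return a `permutation_result` list: `observed`, `null_stats`, `b`,
#'   `m`, `tail`, `p_exact`.
#' @export
permutation_test <- function(values, labels, m = 10000,
                             tail = c("right", "left"), seed = 1L,
                             exhaustive = FALSE) {
  tail <- match.arg(tail)
  if (m < 1) stop("m must be >= 1")
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels")
  g1 <- f == levels(f)[1]
  if (!any(g1) || all(g1)) stop("both groups must be nonempty")
  stat <- function(sel) mean(values[sel]) - mean(values[!sel])
  obs <- stat(g1)
  n <- length(values); n1 <- sum(g1)
  if (exhaustive) {
    combos <- utils::combn(n, n1)
    null_stats <- apply(combos, 2, function(ix) {
      sel <- rep(FALSE, n); sel[ix] <- TRUE; stat(sel)
    })
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    null_stats <- vapply(seq_len(m), function(i) {
      sel <- rep(FALSE, n); sel[sample.int(n, n1)] <- TRUE; stat(sel)
    }, numeric(1))
  }
  mm <- length(null_stats)
  b <- if (tail == "right") sum(null_stats >= obs - 1e-12)
       else sum(null_stats <= obs + 1e-12)
  structure(list(observed = obs, null_stats = null_stats, b = b, m = mm,
                 tail = tail, p_exact = exact_p(b, mm)),
            class = "permutation_result")
}

#' Two-stage adaptive FDR step-up procedure
#'
#' Stage 1 runs a linear step-up at level q' = alpha/(1 + alpha) to
#' estimate the number of true nulls m0 = m - r1; stage 2 reruns the
#' step-up at level q' m / m0.  All p-values are rejected when stage 1
#' rejects everything; nothing is rejected when stage 1 rejects nothing.
#'
#' @param pvals p-values in (0, 1].
#' @param alpha target FDR level.
#' @return list with `critical_p` (largest rejected p; 0 when none) and
#'   `rejected` (logical flags in input order).
#' @export
two_stage_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  step_up <- function(p, q) {
    o <- order(p)
    thr <- q * seq_len(m) / m
    k <- which(p[o] <= thr)
    if (length(k) == 0) return(logical(m))
    out <- logical(m); out[o[seq_len(max(k))]] <- TRUE; out
  }
  q1 <- alpha / (1 + alpha)
  r1 <- sum(step_up(pvals, q1))
  rejected <- if (r1 == 0) logical(m)
              else if (r1 == m) rep(TRUE, m)
              else step_up(pvals, q1 * m / (m - r1))
  list(critical_p = if (any(rejected)) max(pvals[rejected]) else 0,
       rejected = rejected)
}

#' Visual-field amplitude map
#'
#' Regular pixel grid of BOLD amplitudes over degrees of visual angle,
#' covering a rectangular extent (defaults: the screen, -35..35 deg
#' horizontally and -19.75..19.75 deg vertically).
#'
#' @param amplitudes matrix (rows = vertical pixels, cols = horizontal), or
#'   NULL to build an empty map.
#' @param extent_x,extent_y numeric length-2 extents in degrees.
#' @param pixel_deg pixel size in degrees (used when `amplitudes` is NULL).
#' @return a `visual_field_map` list with `amp`, `x`, `y` (pixel centers).
#' @export
visual_field_map <- function(amplitudes = NULL, extent_x = c(-35, 35),
                             extent_y = c(-19.75, 19.75), pixel_deg = 0.5) {
  if (is.null(amplitudes)) {
    nx <- round(diff(extent_x) / pixel_deg)
    ny <- round(diff(extent_y) / pixel_deg)
    amplitudes <- matrix(0, ny, nx)
  }
  ny <- nrow(amplitudes); nx <- ncol(amplitudes)
  structure(list(amp = amplitudes,
                 x = extent_x[1] + (seq_len(nx) - 0.5) * diff(extent_x) / nx,
                 y = extent_y[1] + (seq_len(ny) - 0.5) * diff(extent_y) / ny,
                 extent_x = extent_x, extent_y = extent_y),
            class = "visual_field_map")
}

#' Border specification for the screen-edge artifact test
#' @param thickness_deg border band thickness in degrees.
#' @param n_draws number of random borders in the null distribution.
#' @return a `border_spec` list.
#' @export
border_spec <- function(thickness_deg = 7.2, n_draws = 100000) {
  if (thickness_deg <= 0) stop("thickness must be positive")
  structure(list(thickness_deg = thickness_deg, n_draws = as.integer(n_draws)),
            class = "border_spec")
}

# mean amplitude over a rectangular border band [x0,x1] x [y0,y1] with
# thickness t, restricted to pixels inside the map
band_mean <- function(map, x0, x1, y0, y1, t) {
  xi <- map$x >= x0 & map$x <= x1
  yi <- map$y >= y0 & map$y <= y1
  inner_x <- map$x > x0 + t & map$x < x1 - t
  inner_y <- map$y > y0 + t & map$y < y1 - t
  sel <- outer(yi, xi) & !outer(inner_y, inner_x)
  if (!any(sel)) return(NA_real_)
  mean(map$amp[sel])
}

#' Permutation test for a screen-edge amplitude artifact
#'
#' Observed statistic: mean amplitude within a rectangular band of the
#' given thickness hugging the screen edge.  Null distribution: the same-
#' dimension band translated to centers drawn uniformly over the field,
#' with pixels falling outside the field extent excluded; draws whose band
#' retains no pixels are resampled.  Right-tailed p via the exact-p
#' correction, with ties counting as exceedances.
#'
#' @param map a [visual_field_map()].
#' @param spec a [border_spec()].
#' @param seed integer RNG seed.
#' @return a `permutation_result`.
#' @export
border_test <- function(map, spec = border_spec(), seed = 1L) {
  stopifnot(inherits(map, "visual_field_map"), inherits(spec, "border_spec"))
  t <- spec$thickness_deg
  W <- diff(map$extent_x); H <- diff(map$extent_y)
  if (t > min(W, H) / 2) stop("band thickness exceeds half the field extent")
  obs <- band_mean(map, map$extent_x[1], map$extent_x[2],
                   map$extent_y[1], map$extent_y[2], t)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m <- spec$n_draws
  null_stats <- numeric(m)
  for (i in seq_len(m)) {
    repeat {
      cx <- stats::runif(1, map$extent_x[1], map$extent_x[2])
      cy <- stats::runif(1, map$extent_y[1], map$extent_y[2])
      s <- band_mean(map, cx - W / 2, cx + W / 2, cy - H / 2, cy + H / 2, t)
      if (!is.na(s)) break               # resample draws retaining no pixels
    }
    null_stats[i] <- s
  }
  b <- sum(null_stats >= obs - 1e-12)
  structure(list(observed = obs, null_stats = null_stats, b = b, m = m,
                 tail = "right", p_exact = exact_p(b, m)),
            class = "permutation_result")
}

#' Predicted amplitude modulation by reaction time
#'
#' Convolves a canonical HRF with each of the three task inputs per trial
#' (trial-onset impulse, button-press impulse, time-on-task boxcar), using
#' the measured RTs, and averages the predicted responses within cells
#' crossed by condition (difficulty x accuracy) and a median split of RT
#' within each cell.  Amplitude (max - min) is reported per cell for three
#' model variants: ToT only, TO+BP only, and the sum of all three.
#'
#' @param behavior behavior table with RTs.
#' @param hrf an [hrf_params()]; default [canonical_hrf()].
#' @param window_s trial window for the predicted response, seconds.
#' @param dt working grid step, seconds.
#' @return data.frame with columns `difficulty`, `accuracy`, `rt_group`,
#'   `n`, `tot_only`, `to_bp`, `all three`; cells with < 2 trials are
#'   dropped.
#' @export
rt_modulation_sim <- function(behavior, hrf = canonical_hrf(), window_s = 15,
                              dt = 0.1) {
  b <- behavior[!is.na(behavior$rt_s), , drop = FALSE]
  if (nrow(b) == 0) stop("behavior has no response trials")
  tt <- seq(0, window_s, by = dt)
  kern <- evaluate_hrf(hrf, seq(0, hrf$support_s, by = dt))
  n <- length(tt)
  predict_trial <- function(rt) {
    x_to <- x_bp <- x_tot <- numeric(n)
    bi <- min(max(round(rt / dt) + 1, 1), n)
    x_to[1] <- 1 / dt; x_bp[bi] <- 1 / dt
    if (bi > 1) x_tot[1:(bi - 1)] <- 1
    list(to = conv_causal(x_to, kern) * dt, bp = conv_causal(x_bp, kern) * dt,
         tot = conv_causal(x_tot, kern) * dt)
  }
  cell <- interaction(b$difficulty, b$correct, drop = TRUE)
  rt_group <- rep(NA_character_, nrow(b))
  for (cc in levels(cell)) {
    i <- which(cell == cc)
    med <- stats::median(b$rt_s[i])
    rt_group[i] <- ifelse(b$rt_s[i] <= med, "fast", "slow")
  }
  out <- list()
  for (cc in levels(cell)) for (gg in c("fast", "slow")) {
    i <- which(cell == cc & rt_group == gg)
    if (length(i) < 2) next
    preds <- lapply(b$rt_s[i], predict_trial)
    avg <- function(f) Reduce(`+`, lapply(preds, f)) / length(preds)
    to <- avg(function(p) p$to); bp <- avg(function(p) p$bp)
    tot <- avg(function(p) p$tot)
    out[[paste(cc, gg)]] <- data.frame(
      difficulty = b$difficulty[i[1]], accuracy = b$correct[i[1]],
      rt_group = gg, n = length(i),
      tot_only = response_range(tot), to_bp = response_range(to + bp),
      all_three = response_range(to + bp + tot))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
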