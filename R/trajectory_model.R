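#' Fit the hierarchical Gaussian-process trajectory model
#'
#' Models event-aligned temperature windows `y_iy(t)` (park i, year y, lag t)
#' with a three-level hierarchy: observations follow a GP around the park
#' trajectory with a rough exponential (Ornstein--Uhlenbeck) kernel `k3i`
#' (common range, park-specific variances); park trajectories `u_i(t)` follow
#' a smooth squared-exponential GP `k2` around the population trajectory
#' `w(t)` plus a constant park offset `h_i ~ N(0, tau^2)`; and `w(t)` follows
#' a squared-exponential GP `k1` around a constant `mu`.
#'
#' Inference samples the kernel hyperparameters by adaptive Metropolis on the
#' marginal likelihood with `w`, `u_i` (and `mu`, unless fixed) integrated out
#' analytically; function draws are then recovered by exact conditional
#' Gaussian sampling, which is fast at 61-point lag grids.  With complete
#' (unmasked) windows a balanced sufficient-statistic reduction is used; with
#' masked lags the model conditions on the observed entries only (dense path).
#'
#' @param windows A `lag_windows` object ([align_event_windows()] or
#'   [simulate_trajectory_windows()]).
#' @param priors Optional overrides: `mu_mean`, `mu_sd` (Normal prior on the
#'   top-level constant; defaults: empirical grand mean, 10), `sd_scale`
#'   (half-Normal scale for all kernel SDs; default: empirical SD of the
#'   data), `ls_meanlog`, `ls_sdlog` (log-Normal on length-scales/range;
#'   defaults log 10 days, 0.75).
#' @param sampler List: `chains` (2), `iter` (1200 post-warmup total per
#'   chain incl. warmup), `warmup` (400), `n_fdraws` (number of conditional
#'   function draws, 300), `seed` (1).
#' @param fixed Optional named list fixing hyperparameters (skips MCMC):
#'   `s1, l1` (k1 SD/length-scale), `s2, l2` (k2), `tau`, `rho3` (OU range),
#'   `s3` (vector of per-park OU SDs), optionally `mu`.  Used by the
#'   oracle-equivalence tests and available for sensitivity analysis.
#' @return An object of class `trajectory_fit`: posterior draws of `w(t)`,
#'   `u_i(t)`, `mu` and all hyperparameters; pointwise posterior summaries;
#'   split-Rhat/ESS diagnostics; the data kept for variance partitioning.
#' @export
fit_temperature_trajectory <- function(windows, priors = list(),
                                       sampler = list(), fixed = NULL) {
  stopifnot(inherits(windows, "lag_windows"))
  y <- windows$values
  mask <- windows$mask
  parks <- unique(windows$park)
  P <- length(parks)
  n_obs_rows <- nrow(y)
  if (P < 2 || n_obs_rows < 3)
    stop("hierarchy unidentifiable: need >= 2 parks and >= 3 park-year windows",
         call. = FALSE)
  lag <- windows$lag
  d <- length(lag)
  obs_vals <- y[!mask]
  pr <- modifyList(list(mu_mean = mean(obs_vals), mu_sd = 10,
                        sd_scale = sd(obs_vals),
                        ls_meanlog = log(10), ls_sdlog = 0.75), priors)
  sm <- modifyList(list(chains = 2, iter = 1200, warmup = 400,
                        n_fdraws = 300, seed = 1), sampler)

  balanced <- !any(mask)
  park_of_row <- match(windows$park, parks)
  if (balanced) {
    n_i <- as.integer(table(factor(windows$park, levels = parks)))
    ybar <- matrix(0, P, d)
    Smat <- vector("list", P)
    for (i in seq_len(P)) {
      Yi <- y[park_of_row == i, , drop = FALSE]
      ybar[i, ] <- colMeans(Yi)
      C <- sweep(Yi, 2, ybar[i, ])
      Smat[[i]] <- crossprod(C)
    }
    ybar_vec <- as.vector(t(ybar))
  } else {
    if (sum(!mask) > 4000)
      stop("masked-data (dense) path limited to 4000 observed values; ",
           "drop high-missingness records first", call. = FALSE)
  }

  mu_fixed <- !is.null(fixed$mu)
  par_names <- c("log_s1", "log_l1", "log_s2", "log_l2", "log_tau",
                 "log_rho3", paste0("log_s3_", parks))
  unpack <- function(th) {
    list(s1 = exp(th[1]), l1 = exp(th[2]), s2 = exp(th[3]), l2 = exp(th[4]),
         tau = exp(th[5]), rho3 = exp(th[6]), s3 = exp(th[7:(6 + P)]))
  }
  log_prior <- function(h) {
    lp <- 0
    for (s in c(h$s1, h$s2, h$tau, h$s3))  # half-Normal + log-scale Jacobian
      lp <- lp - 0.5 * (s / pr$sd_scale)^2 + log(s)
    for (l in c(h$l1, h$l2, h$rho3))
      lp <- lp + dnorm(log(l), pr$ls_meanlog, pr$ls_sdlog, log = TRUE)
    lp
  }

  ## marginal covariance of the park-mean vectors (balanced path)
  sigma_ybar <- function(h) {
    K1 <- se_kernel(lag, h$s1^2, h$l1)
    A <- K1 + if (mu_fixed) 0 else pr$mu_sd^2
    K2 <- se_kernel(lag, h$s2^2, h$l2) + h$tau^2
    Sg <- kronecker(matrix(1, P, P), A)
    for (i in seq_len(P)) {
      ii <- ((i - 1) * d + 1):(i * d)
      Sg[ii, ii] <- Sg[ii, ii] + K2 + ou_kernel(lag, h$s3[i]^2, h$rho3) / n_i[i]
    }
    Sg
  }

  loglik_balanced <- function(h) {
    ll <- 0
    for (i in seq_len(P)) {
      K3 <- ou_kernel(lag, h$s3[i]^2, h$rho3)
      R3 <- chol_psd(K3)
      Kinv <- chol2inv(R3)
      ll <- ll - 0.5 * (n_i[i] - 1) * d * log(2 * pi) -
        (n_i[i] - 1) * sum(log(diag(R3))) -
        0.5 * sum(Kinv * Smat[[i]]) - 0.5 * d * log(n_i[i])
    }
    m <- if (mu_fixed) fixed$mu else pr$mu_mean
    ll + mvn_logpdf(ybar_vec, rep(m, P * d), sigma_ybar(h))
  }

  ## dense path over observed entries only
  obs_list <- lapply(seq_len(n_obs_rows), function(r) which(!mask[r, ]))
  sigma_dense <- function(h) {
    K1 <- se_kernel(lag, h$s1^2, h$l1)
    A <- K1 + if (mu_fixed) 0 else pr$mu_sd^2
    K2 <- se_kernel(lag, h$s2^2, h$l2) + h$tau^2
    K3 <- lapply(seq_len(P), function(i) ou_kernel(lag, h$s3[i]^2, h$rho3))
    sizes <- lengths(obs_list)
    N <- sum(sizes)
    Sg <- matrix(0, N, N)
    off <- cumsum(c(0, sizes))
    for (r in seq_len(n_obs_rows)) for (q in seq_len(n_obs_rows)) {
      sr <- obs_list[[r]]; sq <- obs_list[[q]]
      B <- A[sr, sq, drop = FALSE]
      if (park_of_row[r] == park_of_row[q]) {
        B <- B + K2[sr, sq, drop = FALSE]
        if (r == q) B <- B + K3[[park_of_row[r]]][sr, sq, drop = FALSE]
      }
      Sg[(off[r] + 1):off[r + 1], (off[q] + 1):off[q + 1]] <- B
    }
    Sg
  }
  y_dense <- if (!balanced) unlist(lapply(seq_len(n_obs_rows), function(r)
    y[r, obs_list[[r]]])) else NULL

  loglik <- function(h) {
    if (balanced) loglik_balanced(h)
    else {
      m <- if (mu_fixed) fixed$mu else pr$mu_mean
      mvn_logpdf(y_dense, rep(m, length(y_dense)), sigma_dense(h))
    }
  }
  logpost <- function(th) {
    h <- unpack(th)
    lp <- log_prior(h)
    if (!is.finite(lp)) return(-Inf)
    ll <- tryCatch(loglik(h), error = function(e) -Inf)
    lp + ll
  }

  if (is.null(fixed)) {
    init <- log(c(0.5 * pr$sd_scale, 10, 0.3 * pr$sd_scale, 10,
                  0.3 * pr$sd_scale, 3, rep(0.5 * pr$sd_scale, P)))
    run <- am_run(logpost, init, n_iter = sm$iter, n_warmup = sm$warmup,
                  chains = sm$chains, seed = sm$seed, param_names = par_names,
                  blocks = list(1:6, 6 + seq_len(P)))
    hyper_draws <- run$draws
    diagnostics <- run$diagnostics
  } else {
    th <- log(c(fixed$s1, fixed$l1, fixed$s2, fixed$l2, fixed$tau,
                fixed$rho3, rep(fixed$s3, length.out = P)))
    hyper_draws <- matrix(rep(th, each = sm$n_fdraws), sm$n_fdraws,
                          length(th), dimnames = list(NULL, par_names))
    diagnostics <- list(rhat = NULL, ess = NULL, note = "hyperparameters fixed")
  }

  ## conditional Gaussian recovery of (mu, w, u_i) given hyperparameters
  cond_moments <- function(h) {
    K1 <- se_kernel(lag, h$s1^2, h$l1)
    A <- K1 + if (mu_fixed) 0 else pr$mu_sd^2
    K2 <- se_kernel(lag, h$s2^2, h$l2) + h$tau^2
    has_mu <- !mu_fixed
    q <- (if (has_mu) 1L else 0L) + d + P * d
    Cgg <- matrix(0, q, q)
    wi <- (if (has_mu) 1L else 0L) + seq_len(d)
    ui <- function(i) (if (has_mu) 1L else 0L) + d + ((i - 1) * d + 1):(i * d)
    if (has_mu) {
      Cgg[1, 1] <- pr$mu_sd^2
      Cgg[1, -1] <- pr$mu_sd^2
      Cgg[-1, 1] <- pr$mu_sd^2
    }
    Cgg[wi, wi] <- A
    for (i in seq_len(P)) {
      Cgg[wi, ui(i)] <- A; Cgg[ui(i), wi] <- A
      for (j in seq_len(P)) {
        Cgg[ui(i), ui(j)] <- A + if (i == j) K2 else 0
      }
    }
    m0 <- if (mu_fixed) fixed$mu else pr$mu_mean
    mg <- rep(m0, q)
    if (balanced) {
      Sy <- sigma_ybar(h)
      Cgy <- matrix(0, q, P * d)
      for (j in seq_len(P)) {
        jj <- ((j - 1) * d + 1):(j * d)
        if (has_mu) Cgy[1, jj] <- pr$mu_sd^2
        Cgy[wi, jj] <- A
        for (i in seq_len(P)) Cgy[ui(i), jj] <- A + if (i == j) K2 else 0
      }
      yv <- ybar_vec
    } else {
      Sy <- sigma_dense(h)
      sizes <- lengths(obs_list)
      off <- cumsum(c(0, sizes))
      Cgy <- matrix(0, q, sum(sizes))
      for (r in seq_len(n_obs_rows)) {
        sr <- obs_list[[r]]; cols <- (off[r] + 1):off[r + 1]
        if (has_mu) Cgy[1, cols] <- pr$mu_sd^2
        Cgy[wi, cols] <- A[, sr, drop = FALSE]
        for (i in seq_len(P))
          Cgy[ui(i), cols] <- A[, sr, drop = FALSE] +
            if (i == park_of_row[r]) K2[, sr, drop = FALSE] else 0
      }
      yv <- y_dense
    }
    Ry <- chol_psd(Sy)
    W <- backsolve(Ry, t(Cgy), transpose = TRUE)          # Ry^-T Cgy^T
    mean_g <- mg + drop(crossprod(W, backsolve(Ry, yv - rep(if (mu_fixed) fixed$mu else pr$mu_mean, length(yv)), transpose = TRUE)))
    cov_g <- Cgg - crossprod(W)
    list(mean = mean_g, cov = cov_g, has_mu = has_mu)
  }

  S <- min(sm$n_fdraws, nrow(hyper_draws))
  keep_idx <- unique(round(seq(1, nrow(hyper_draws), length.out = S)))
  S <- length(keep_idx)
  w_draws <- matrix(NA_real_, S, d)
  u_draws <- array(NA_real_, c(S, P, d))
  mu_draws <- numeric(S)
  w_mean_acc <- numeric(d)       # Rao-Blackwellized posterior means
  u_mean_acc <- matrix(0, P, d)
  analytic <- NULL
  with_seed(split_seed(sm$seed, "traj_fdraws"), {
    last_theta <- NULL
    cm <- NULL
    for (s in seq_len(S)) {
      th <- hyper_draws[keep_idx[s], ]
      if (is.null(last_theta) || any(th != last_theta)) {
        cm <- cond_moments(unpack(th))
        last_theta <- th
      }
      g <- mvn_draw(cm$mean, cm$cov)
      off_mu <- if (cm$has_mu) 1L else 0L
      w_mean_acc <- w_mean_acc + cm$mean[off_mu + seq_len(d)] / S
      for (i in seq_len(P))
        u_mean_acc[i, ] <- u_mean_acc[i, ] +
          cm$mean[off_mu + d + ((i - 1) * d + 1):(i * d)] / S
      if (cm$has_mu) {
        mu_draws[s] <- g[1]
        w_draws[s, ] <- g[1 + seq_len(d)]
        for (i in seq_len(P)) u_draws[s, i, ] <- g[1 + d + ((i - 1) * d + 1):(i * d)]
      } else {
        mu_draws[s] <- fixed$mu
        w_draws[s, ] <- g[seq_len(d)]
        for (i in seq_len(P)) u_draws[s, i, ] <- g[d + ((i - 1) * d + 1):(i * d)]
      }
    }
    if (!is.null(fixed)) {
      off <- if (mu_fixed) 0L else 1L
      analytic <- list(w_mean = cm$mean[off + seq_len(d)],
                        u_mean = t(vapply(seq_len(P), function(i)
                          cm$mean[off + d + ((i - 1) * d + 1):(i * d)], numeric(d))),
                        mu_mean = if (mu_fixed) fixed$mu else cm$mean[1],
                        w_sd = sqrt(pmax(0, diag(cm$cov)[off + seq_len(d)])))
    }
  })

  post <- list(
    w_mean = w_mean_acc,
    w_q05 = apply(w_draws, 2, quantile, 0.05),
    w_q95 = apply(w_draws, 2, quantile, 0.95),
    w_sd = apply(w_draws, 2, sd),
    u_mean = u_mean_acc,
    mu_mean = mean(mu_draws))
  structure(list(lag = lag, park_id = parks,
                 draws = list(hyper = hyper_draws[keep_idx, , drop = FALSE],
                              mu = mu_draws, w = w_draws, u = u_draws),
                 post = post, analytic = analytic,
                 diagnostics = diagnostics,
                 data = list(values = y, mask = mask,
                             total_var = var(obs_vals),
                             n_rows = n_obs_rows),
                 priors = pr, fixed = fixed),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %d parks | lags %d..%d | %d function draws\n",
              length(x$park_id), min(x$lag), max(x$lag), nrow(x$draws$w)))
  s <- event_day_climate_summary(x)
  cat(sprintf("  w(0) = %.2f (+/- %.2f) | slope at lag 0 = %.3f per day\n",
              s$value, s$posterior_sd, s$slope))
  invisible(x)
}

#' Partition observed window variance into shared, park, and idiosyncratic
#' components
#'
#' The shared component is the variance over the lag grid of the posterior
#' mean population trajectory `w(t)` divided by the total empirical variance
#' of all observed window values; the additional park component is the mean
#' over parks of the variance of `E[u_i] - E[w]` over the grid, divided by the
#' same total; the idiosyncratic component is the remainder.  A draw-wise
#' variant (averaging the same ratios over posterior draws) is exposed for
#' sensitivity.
#'
#' @param windows The `lag_windows` the model was fitted to.
#' @param fit The corresponding `trajectory_fit`.
#' @param method `"plugin"` (posterior means; default) or `"draws"`.
#' @return Named numeric vector `c(shared=, park_additional=, idiosyncratic=)`
#'   in percent, summing to 100.
#' @export
variance_partition <- function(windows, fit, method = c("plugin", "draws")) {
  method <- match.arg(method)
  total <- var(windows$values[!windows$mask])
  if (!is.finite(total) || total <= 0)
    stop("total variance of the observed windows is zero; partition undefined",
         call. = FALSE)
  if (method == "plugin") {
    shared <- var(fit$post$w_mean) / total * 100
    parkadd <- mean(vapply(seq_along(fit$park_id), function(i)
      var(fit$post$u_mean[i, ] - fit$post$w_mean), 0.0)) / total * 100
  } else {
    S <- nrow(fit$draws$w)
    sh <- vapply(seq_len(S), function(s) var(fit$draws$w[s, ]), 0.0)
    pa <- vapply(seq_len(S), function(s)
      mean(vapply(seq_along(fit$park_id), function(i)
        var(fit$draws$u[s, i, ] - fit$draws$w[s, ]), 0.0)), 0.0)
    shared <- mean(sh) / total * 100
    parkadd <- mean(pa) / total * 100
  }
  c(shared = shared, park_additional = parkadd,
    idiosyncratic = 100 - shared - parkadd)
}

#' Expected climate at the event day and its local slope
#'
#' For a `trajectory_fit`, reports the posterior mean and SD of the population
#' trajectory at lag 0 (both the posterior SD of the mean trajectory and a
#' predictive SD that adds the spread of the park trajectories), and the
#' local slope of the posterior-mean trajectory at lag 0 by central
#' difference.  For a `snow_trajectory_summary`, reports the smoothed global
#' mean at lag 0 and its central-difference slope.
#'
#' @param fit A `trajectory_fit` or `snow_trajectory_summary`.
#' @return A list with `value`, `posterior_sd` (NA for snow), `predictive_sd`
#'   (NA for snow), and `slope` (per day).
#' @export
event_day_climate_summary <- function(fit) {
  if (inherits(fit, "trajectory_fit")) {
    i0 <- match(0L, fit$lag)
    if (is.na(i0)) stop("lag grid does not contain 0", call. = FALSE)
    im <- match(-1L, fit$lag); ip <- match(1L, fit$lag)
    slope <- if (!is.na(im) && !is.na(ip))
      (fit$post$w_mean[ip] - fit$post$w_mean[im]) / 2 else NA_real_
    u0 <- fit$draws$u[, , i0, drop = FALSE]
    list(value = fit$post$w_mean[i0],
         posterior_sd = fit$post$w_sd[i0],
         predictive_sd = sd(as.vector(u0)),
         slope = slope)
  } else if (inherits(fit, "snow_trajectory_summary")) {
    i0 <- match(0L, fit$lag)
    im <- match(-1L, fit$lag); ip <- match(1L, fit$lag)
    slope <- if (!is.na(im) && !is.na(ip))
      (fit$w_hat[ip] - fit$w_hat[im]) / 2 else NA_real_
    list(value = fit$w_hat[i0], posterior_sd = NA_real_,
         predictive_sd = NA_real_, slope = slope)
  } else stop("unsupported fit object", call. = FALSE)
}

#' Loess-smoothed snow trajectory summary
#'
#' Snow dynamics (spiky accumulation, slow compaction, fast melt) defeat the
#' smooth GP model, so the snow analysis is exploratory: per park the raw mean
#' trajectory over years `vbar_i(t)` (missing lags excluded from the mean), a
#' loess smooth `uhat_i(t)` of it, and the global mean
#' `what(t) = mean_i uhat_i(t)`.  Smoothed values are clipped at zero
#' (documented), after which `what` is recomputed so that it always equals the
#' park mean of the clipped `uhat_i`.
#'
#' @param windows A snow `lag_windows` object.
#' @param loess_span Loess span over the 61-lag grid (default 0.3).
#' @return An object of class `snow_trajectory_summary`: `lag`, `vbar`
#'   (parks x lags), `u_hat`, `w_hat`, `span`, `n_parks`, `low_support`
#'   (parks with < 3 years, computed but flagged).
#' @export
snow_trajectory_summary <- function(windows, loess_span = 0.3) {
  stopifnot(inherits(windows, "lag_windows"))
  parks <- unique(windows$park)
  P <- length(parks)
  if (P < 1 || nrow(windows$values) < 1)
    stop("no snow windows available", call. = FALSE)
  d <- length(windows$lag)
  vals <- windows$values
  vals[windows$mask] <- NA
  vbar <- matrix(NA_real_, P, d, dimnames = list(parks, NULL))
  u_hat <- vbar
  n_years <- integer(P)
  for (i in seq_len(P)) {
    Yi <- vals[windows$park == parks[i], , drop = FALSE]
    n_years[i] <- nrow(Yi)
    vbar[i, ] <- colMeans(Yi, na.rm = TRUE)
    ok <- is.finite(vbar[i, ])
    fit <- loess(y ~ t, data = data.frame(t = windows$lag[ok], y = vbar[i, ok]),
                 span = loess_span, surface = "direct")
    u_hat[i, ] <- pmax(0, predict(fit, newdata = data.frame(t = windows$lag)))
  }
  structure(list(lag = windows$lag, vbar = vbar, u_hat = u_hat,
                 w_hat = colMeans(u_hat), span = loess_span, n_parks = P,
                 n_years = setNames(n_years, parks),
                 low_support = setNames(n_years < 3, parks)),
            class = "snow_trajectory_summary")
}

#' @export
print.snow_trajectory_summary <- function(x, ...) {
  cat(sprintf("<snow_trajectory_summary> %d parks | span %.2f | what(0) = %.1f cm\n",
              x$n_parks, x$span, x$w_hat[match(0L, x$lag)]))
  if (any(x$low_support))
    cat("  low-support parks (< 3 years):",
        paste(names(which(x$low_support)), collapse = ", "), "\n")
  invisible(x)
}
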