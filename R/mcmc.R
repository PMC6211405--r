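## Blocked adaptive random-walk Metropolis for low-dimensional hyperparameter
## posteriors.  Both hierarchical models in this package integrate their
## Gaussian function values out analytically, leaving O(10-25) hyperparameters
## on unconstrained (log) scales.  Parameters are updated in caller-defined
## blocks (e.g. structural kernel parameters vs per-park residual scales);
## each block carries its own adaptive proposal covariance and scale, with
## diminishing adaptation (Roberts & Rosenthal) so the chain remains ergodic.

am_chain <- function(logpost, init, n_iter, n_warmup, blocks = NULL,
                     scale0 = 0.1, target_accept = 0.3) {
  d <- length(init)
  if (is.null(blocks)) blocks <- list(seq_len(d))
  nb <- length(blocks)
  draws <- matrix(NA_real_, n_iter, d)
  lp <- numeric(n_iter)
  x <- init
  lx <- logpost(x)
  if (!is.finite(lx)) stop("log posterior not finite at initial value", call. = FALSE)
  st <- lapply(blocks, function(b) {
    db <- length(b)
    list(mu = x[b], cov = diag(scale0^2, db), R = diag(scale0, db),
         loglam = log(2.38^2 / db), acc = 0L)
  })
  n_acc <- 0L
  for (i in seq_len(n_iter)) {
    for (k in seq_len(nb)) {
      b <- blocks[[k]]
      prop <- x
      prop[b] <- x[b] +
        drop(t(st[[k]]$R) %*% rnorm(length(b))) * exp(st[[k]]$loglam / 2)
      lprop <- logpost(prop)
      acc <- is.finite(lprop) && log(runif(1)) < lprop - lx
      if (acc) {
        x <- prop; lx <- lprop
        st[[k]]$acc <- st[[k]]$acc + 1L
        n_acc <- n_acc + 1L
      }
      ## diminishing adaptation
      w <- min(0.9, 3 * i^-0.7)
      st[[k]]$loglam <- st[[k]]$loglam +
        w * ((if (acc) 1 else 0) - target_accept)
      st[[k]]$mu <- st[[k]]$mu + w * (x[b] - st[[k]]$mu)
      st[[k]]$cov <- st[[k]]$cov +
        w * (tcrossprod(x[b] - st[[k]]$mu) - st[[k]]$cov)
      if (i %% 20 == 0) {
        db <- length(b)
        S <- st[[k]]$cov + diag(1e-9 + 1e-6 * mean(diag(st[[k]]$cov)), db)
        st[[k]]$R <- tryCatch(chol(S), error = function(e) st[[k]]$R)
      }
    }
    draws[i, ] <- x
    lp[i] <- lx
  }
  keep <- (n_warmup + 1):n_iter
  list(draws = draws[keep, , drop = FALSE], lp = lp[keep],
       accept_rate = n_acc / (n_iter * nb))
}

## Run `chains` independent chains; returns stacked draws plus diagnostics.
## `optim_steps` > 0 first climbs toward the posterior mode (Nelder-Mead,
## deterministic); off by default — with weak identification the mode can sit
## away from the typical set.
am_run <- function(logpost, init, n_iter = 1500, n_warmup = 500,
                   chains = 2, seed = 1, scale0 = 0.1, param_names = NULL,
                   blocks = NULL, optim_steps = 0) {
  if (optim_steps > 0) {
    opt <- tryCatch(
      optim(init, function(th) -logpost(th), method = "Nelder-Mead",
            control = list(maxit = optim_steps)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) init <- opt$par
  }
  chains_out <- vector("list", chains)
  for (cc in seq_len(chains)) {
    with_seed(split_seed(seed, 7001L, cc), {
      init_c <- init + if (cc == 1) 0 else rnorm(length(init), 0, 0.1)
      chains_out[[cc]] <- am_chain(logpost, init_c, n_iter, n_warmup, blocks,
                                   scale0)
    })
  }
  draw_list <- lapply(chains_out, `[[`, "draws")
  draws <- do.call(rbind, draw_list)
  if (!is.null(param_names)) colnames(draws) <- param_names
  rhat <- apply_rhat(draw_list)
  ess <- vapply(seq_len(ncol(draws)), function(j)
    sum(vapply(draw_list, function(D) ess_basic(D[, j]), 0.0)), 0.0)
  if (!is.null(param_names)) names(rhat) <- names(ess) <- param_names
  if (any(rhat > 1.05, na.rm = TRUE))
    warning(sprintf("split-Rhat > 1.05 for %d parameter(s); consider longer chains",
                    sum(rhat > 1.05, na.rm = TRUE)), call. = FALSE)
  list(draws = draws,
       accept_rate = mean(vapply(chains_out, `[[`, 0.0, "accept_rate")),
       diagnostics = list(rhat = rhat, ess = ess,
                          n_chains = chains, n_kept = nrow(draws)))
}

## split-Rhat over a list of per-chain draw matrices (one parameter at a time)
apply_rhat <- function(draw_list) {
  p <- ncol(draw_list[[1]])
  vapply(seq_len(p), function(j) {
    halves <- list()
    for (D in draw_list) {
      n <- nrow(D)
      h <- floor(n / 2)
      halves <- c(halves, list(D[1:h, j], D[(n - h + 1):n, j]))
    }
    rhat_chains(halves)
  }, 0.0)
}

rhat_chains <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, 0.0)
  vars <- vapply(chains, var, 0.0)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## effective sample size via initial positive sequence of autocovariances
ess_basic <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(NA_real_)
  rho <- drop(acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
  s <- 0
  k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}
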