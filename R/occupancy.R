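#' Construct a detection array
#'
#' Binary detections `y[taxon, site, sample, marker]` with a per-site depth
#' covariate. Sites are station x sampling-depth combinations, samples are
#' replicate water bottles within a site, markers are the PCR primer sets.
#' `NA` marks replicate x marker combinations that were not sequenced; the
#' missing pattern must be identical across taxa.
#'
#' @param y 4-d array (taxon x site x sample x marker) of 0/1/`NA`.
#' @param depth_m Numeric vector of site depths in meters (length = number
#'   of sites).
#' @return Object of class `"detection_array"`.
#' @export
detection_array <- function(y, depth_m) {
  if (length(dim(y)) != 4L) stop("detection_array: y must be a 4-d array")
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop("detection_array: y entries must be 0, 1 or NA")
  }
  if (length(depth_m) != dim(y)[2L]) {
    stop("detection_array: depth_m must have one entry per site")
  }
  # missing pattern identical across taxa
  na1 <- is.na(y[1L, , , , drop = FALSE])
  for (k in seq_len(dim(y)[1L])) {
    if (!identical(unname(is.na(y[k, , , , drop = FALSE])), unname(na1))) {
      stop("detection_array: missing pattern must be identical across taxa")
    }
  }
  if (is.null(dimnames(y))) {
    dimnames(y) <- list(paste0("taxon", seq_len(dim(y)[1L])),
                        paste0("site", seq_len(dim(y)[2L])),
                        paste0("sample", seq_len(dim(y)[3L])),
                        paste0("marker", seq_len(dim(y)[4L])))
  }
  structure(list(y = y, depth_m = as.numeric(depth_m)),
            class = "detection_array")
}

#' Build a detection array from pipeline tables
#'
#' Collapses read counts to binary detections at a chosen taxonomic rank:
#' `y = 1` iff at least one read of an ESV assigned to the taxon occurs in
#' replicate `j` at site `i` with marker `m`. Sites are station x location
#' combinations from the metadata (controls excluded); replicates are the
#' water samples within a site, ordered by sample id; a replicate x marker
#' cell with no row at all in the ESV table is recorded `NA` (not
#' sequenced).
#'
#' @param assignments Assignment data frame (see [assign_taxonomy()]).
#' @param esv_table Long-format ESV table with `marker` column.
#' @param metadata Sample metadata.
#' @param rank `"species"` or `"family"`: taxa are the distinct names at
#'   this rank (family-level aggregates congeneric species).
#' @return A [detection_array()].
#' @export
build_detection_array <- function(assignments, esv_table, metadata,
                                  rank = c("species", "family")) {
  rank <- match.arg(rank)
  meta <- metadata[!metadata$is_control, , drop = FALSE]
  site_key <- paste(meta$station, meta$location, sep = ":")
  sites <- unique(site_key)
  depth_site <- tapply(meta$depth_m, factor(site_key, levels = sites), mean)
  # replicate index within site
  j_of_sample <- stats::ave(seq_len(nrow(meta)), site_key, FUN = seq_along)
  J <- max(j_of_sample)
  markers <- sort(unique(esv_table$marker))
  asg <- assignments[!is.na(assignments[[rank]]), , drop = FALSE]
  taxa <- sort(unique(asg[[rank]]))
  if (length(taxa) == 0L) stop("build_detection_array: no taxa named at rank ", rank)

  K <- length(taxa); I <- length(sites); M <- length(markers)
  y <- array(NA_real_, dim = c(K, I, J, M),
             dimnames = list(taxa, sites, paste0("rep", seq_len(J)), markers))
  # cells that were sequenced: any row for (sample, marker)
  seq_key <- unique(paste(esv_table$sample_id, esv_table$marker, sep = "\r"))
  for (s in seq_len(nrow(meta))) {
    i <- match(site_key[s], sites)
    j <- j_of_sample[s]
    for (m in seq_len(M)) {
      if (paste(meta$sample_id[s], markers[m], sep = "\r") %in% seq_key) {
        y[, i, j, m] <- 0
      }
    }
  }
  reads <- esv_table[esv_table$read_count > 0, , drop = FALSE]
  reads <- reads[reads$esv_id %in% asg$esv_id &
                   reads$sample_id %in% meta$sample_id, , drop = FALSE]
  if (nrow(reads) > 0L) {
    k <- match(asg[[rank]][match(reads$esv_id, asg$esv_id)], taxa)
    s <- match(reads$sample_id, meta$sample_id)
    i <- match(site_key[s], sites)
    j <- j_of_sample[s]
    m <- match(reads$marker, markers)
    y[cbind(k, i, j, m)] <- 1
  }
  n_missing <- sum(is.na(y[1L, , , ]))
  if (n_missing > 0L) {
    message("build_detection_array: ", n_missing,
            " replicate x marker cell(s) not sequenced, recorded NA")
  }
  detection_array(y, as.numeric(depth_site))
}

#' Priors for the multi-scale occupancy model
#'
#' Community hyperpriors: means `mu ~ Normal(0, mu_sd^2)` on the logit
#' scale and scales `sigma ~ Half-Normal(sigma_scale)`; weakly informative
#' defaults.
#'
#' @param mu_mean,mu_sd Normal prior on community means (default 0, 2).
#' @param sigma_scale Half-normal scale for community SDs (default 1).
#' @return List of class `"occupancy_priors"`.
#' @export
occupancy_priors <- function(mu_mean = 0, mu_sd = 2, sigma_scale = 1) {
  stopifnot(mu_sd > 0, sigma_scale > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_scale = sigma_scale), class = "occupancy_priors")
}

#' Fit the multi-species, multi-scale occupancy model
#'
#' Hierarchical model separating occupancy, availability and detection:
#' \deqn{z_{ik} \sim Bern(\psi_{ik}), \quad logit(\psi_{ik}) = \beta_{0k} +
#'   \beta_{1k}\, \tilde d_i}
#' \deqn{a_{ijk} \mid z_{ik} \sim Bern(z_{ik}\,\theta_k)}
#' \deqn{y_{ijmk} \mid a_{ijk} \sim Bern(a_{ijk}\,p_{mk}), \quad
#'   logit(p_{mk}) = \alpha_{mk}}
#' with depth (standardized to mean 0, SD 1) as the occupancy covariate and
#' primer set as the detection covariate. Taxon-level parameters are drawn
#' from community normal hyperpriors (per-marker for `alpha`). Fitting is
#' by Metropolis-within-Gibbs MCMC with latent-state (`z`, `a`)
#' augmentation: closed-form Bernoulli full conditionals for the latent
#' states and conjugate updates for the community means; random-walk
#' Metropolis (scales adapted during burn-in only) for logit-scale
#' coefficients and community SDs.
#'
#' @param darr A [detection_array()].
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iters Total iterations per chain (including burn-in).
#' @param burnin Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. Identical seed
#'   and configuration give identical draws.
#' @param priors An [occupancy_priors()] object.
#' @param include_depth Include the depth covariate on occupancy?
#' @param fix_theta,fix_p Optionally fix availability and/or detection
#'   probability at a constant (e.g. 1 for the perfect-detection limit)
#'   instead of estimating them.
#' @return Object of class `"occupancy_fit"`: `draws` (list of per-chain
#'   matrices, iterations x parameters), `summary` (see
#'   [summarize_posterior()]), `converged` (all R-hat < 1.1), and the data
#'   dimensions. A convergence failure is flagged with a warning, never
#'   silently.
#' @export
fit_occupancy <- function(darr, chains = 4L, iters = 2000L, burnin = 1000L,
                          thin = 1L, seed = 1L,
                          priors = occupancy_priors(),
                          include_depth = TRUE,
                          fix_theta = NULL, fix_p = NULL) {
  stopifnot(inherits(darr, "detection_array"))
  if (chains < 2L) warning("fit_occupancy: fewer than 2 chains, R-hat unavailable")
  if (burnin >= iters) stop("fit_occupancy: burnin must be < iters")
  y <- darr$y
  if (!all(y %in% c(0, 1) | is.na(y))) stop("fit_occupancy: non-binary y")
  dms <- dim(y)
  K <- dms[1L]; I <- dms[2L]; J <- dms[3L]; M <- dms[4L]
  taxa <- dimnames(y)[[1L]]; markers <- dimnames(y)[[4L]]
  d_std <- if (stats::sd(darr$depth_m) > 0) {
    as.numeric(scale(darr$depth_m))
  } else {
    rep(0, I)
  }

  draws <- lapply(seq_len(chains), function(ch) {
    run_occupancy_chain(y, d_std, iters = iters, burnin = burnin,
                        thin = thin, seed = seed + ch - 1L, priors = priors,
                        include_depth = include_depth,
                        fix_theta = fix_theta, fix_p = fix_p,
                        taxa = taxa, markers = markers)
  })
  smry <- summarize_posterior(draws)
  converged <- all(smry$rhat < 1.1, na.rm = TRUE) && chains >= 2L
  if (!converged) {
    warning("fit_occupancy: R-hat >= 1.1 for some parameters (or < 2 chains); ",
            "inspect $summary before use")
  }
  structure(list(draws = draws, summary = smry, converged = converged,
                 dims = c(K = K, I = I, J = J, M = M),
                 taxa = taxa, markers = markers,
                 depth_mean = mean(darr$depth_m),
                 depth_sd = stats::sd(darr$depth_m),
                 include_depth = include_depth,
                 fix_theta = fix_theta, fix_p = fix_p,
                 mcmc = c(chains = chains, iters = iters, burnin = burnin,
                          thin = thin, seed = seed)),
            class = "occupancy_fit")
}

# One MCMC chain. Vectorized over taxa and cells; replicate cells that were
# never sequenced for any marker are excluded from the likelihood.
run_occupancy_chain <- function(y, d_std, iters, burnin, thin, seed, priors,
                                include_depth, fix_theta, fix_p,
                                taxa, markers) {
  set.seed(seed)
  K <- dim(y)[1L]; I <- dim(y)[2L]; J <- dim(y)[3L]; M <- dim(y)[4L]
  IJ <- I * J
  site_of_ij <- rep(seq_len(I), times = J)  # ij index = i + (j-1)*I
  # Y[k, ij, m]; obs[ij, m] observation mask
  Y <- array(y, dim = c(K, IJ, M))
  obs <- matrix(as.numeric(!is.na(array(y[1L, , , ], dim = c(IJ, M)))), IJ, M)
  Y[is.na(Y)] <- 0
  exist <- rowSums(obs) > 0          # replicate was sequenced at all
  n_exist_i <- as.numeric(rowsum(as.numeric(exist), site_of_ij))
  anyY <- matrix(0, K, IJ)
  for (m in seq_len(M)) anyY <- pmax(anyY, Y[, , m])
  anyY_site <- t(rowsum(t(anyY), site_of_ij)) > 0  # K x I
  site_ind <- outer(site_of_ij, seq_len(I), `==`) * 1  # IJ x I

  theta_fixed <- !is.null(fix_theta)
  p_fixed <- !is.null(fix_p)

  # initial values (chain-jittered)
  beta0 <- stats::qnorm(pmin(pmax(rowMeans(anyY_site), 0.05), 0.95)) +
    stats::rnorm(K, 0, 0.3)
  beta1 <- if (include_depth) stats::rnorm(K, 0, 0.3) else rep(0, K)
  ltheta <- if (theta_fixed) rep(stats::qlogis(min(max(fix_theta, 1e-12),
                                                  1 - 1e-12)), K)
  else stats::qlogis(0.7) + stats::rnorm(K, 0, 0.3)
  alpha <- if (p_fixed) matrix(stats::qlogis(min(max(fix_p, 1e-12), 1 - 1e-12)),
                               K, M)
  else matrix(stats::rnorm(K * M, 0, 0.5), K, M)
  mu_b0 <- mean(beta0); sig_b0 <- 1
  mu_b1 <- 0; sig_b1 <- 1
  mu_lt <- stats::qlogis(0.7); sig_lt <- 1
  mu_a <- colMeans(alpha); sig_a <- rep(1, M)
  z <- (anyY_site * 1)
  a <- anyY

  # RW proposal scales, adapted during burn-in only
  s_a <- 0.5; s_b0 <- 0.5; s_b1 <- 0.5; s_lt <- 0.5; s_sig <- 0.4
  acc <- c(a = 0, b0 = 0, b1 = 0, lt = 0, sig = 0)
  n_prop <- c(a = 0, b0 = 0, b1 = 0, lt = 0, sig = 0)

  par_names <- c(paste0("beta0[", taxa, "]"),
                 if (include_depth) paste0("beta1[", taxa, "]"),
                 if (!theta_fixed) paste0("theta[", taxa, "]"),
                 if (!p_fixed) paste0("alpha[", rep(taxa, times = M), ",",
                                      rep(markers, each = K), "]"),
                 "mu_beta0", "sigma_beta0",
                 if (include_depth) c("mu_beta1", "sigma_beta1"),
                 if (!theta_fixed) c("mu_logit_theta", "sigma_logit_theta"),
                 if (!p_fixed) c(paste0("mu_alpha[", markers, "]"),
                                 paste0("sigma_alpha[", markers, "]")))
  keep <- seq(burnin + 1L, iters, by = thin)
  out <- matrix(NA_real_, length(keep), length(par_names),
                dimnames = list(NULL, par_names))
  row <- 0L

  half_normal_lp <- function(s, scale) stats::dnorm(s, 0, scale, log = TRUE)
  mu0 <- priors$mu_mean; s0 <- priors$mu_sd; hs <- priors$sigma_scale

  update_sigma <- function(sig, vals, mu) {
    ls <- log(sig)
    ls_new <- ls + stats::rnorm(1, 0, s_sig)
    s_new <- exp(ls_new)
    logr <- sum(stats::dnorm(vals, mu, s_new, log = TRUE)) -
      sum(stats::dnorm(vals, mu, sig, log = TRUE)) +
      half_normal_lp(s_new, hs) - half_normal_lp(sig, hs) +
      ls_new - ls  # Jacobian of the log transform
    accepted <- log(stats::runif(1)) < logr
    list(sig = if (accepted) s_new else sig, acc = accepted)
  }
  update_mu <- function(vals, sig) {
    n <- length(vals)
    prec <- n / sig^2 + 1 / s0^2
    m <- (sum(vals) / sig^2 + mu0 / s0^2) / prec
    stats::rnorm(1, m, sqrt(1 / prec))
  }

  for (it in seq_len(iters)) {
    theta <- stats::plogis(ltheta)
    p <- stats::plogis(alpha)

    ## latent a | z, y
    logQ <- log1p(-p) %*% t(obs)               # K x IJ
    th <- matrix(theta, K, IJ)
    prnum <- th * exp(logQ)
    pra <- prnum / (prnum + 1 - th)
    Zx <- z[, site_of_ij, drop = FALSE]
    U <- matrix(stats::runif(K * IJ), K, IJ)
    a <- ifelse(anyY > 0, 1, (U < pra) * Zx)
    a[, !exist] <- 0

    ## latent z | a
    anyA <- (a %*% site_ind) > 0               # K x I
    psi <- stats::plogis(outer(beta0, rep(1, I)) + outer(beta1, d_std))
    Q0 <- exp(outer(log1p(-theta), n_exist_i)) # (1-theta)^n_i
    prz <- psi * Q0 / (psi * Q0 + 1 - psi)
    U <- matrix(stats::runif(K * I), K, I)
    z <- ifelse(anyA, 1, (U < prz) * 1)

    ## theta (availability), vectorized MH on the logit scale
    if (!theta_fixed) {
      T1 <- rowSums(a)
      Zj <- drop(z %*% n_exist_i)
      lt_new <- ltheta + stats::rnorm(K, 0, s_lt)
      ll <- function(lt) {
        th2 <- stats::plogis(lt)
        T1 * log(th2) + (Zj - T1) * log1p(-th2) +
          stats::dnorm(lt, mu_lt, sig_lt, log = TRUE)
      }
      accv <- log(stats::runif(K)) < (ll(lt_new) - ll(ltheta))
      ltheta[accv] <- lt_new[accv]
      acc["lt"] <- acc["lt"] + mean(accv); n_prop["lt"] <- n_prop["lt"] + 1
    }

    ## alpha (detection), vectorized MH over (taxon, marker)
    if (!p_fixed) {
      n1 <- matrix(0, K, M); n0 <- matrix(0, K, M)
      for (m in seq_len(M)) {
        w <- obs[, m]
        n1[, m] <- drop((a * Y[, , m]) %*% w)
        n0[, m] <- drop(a %*% w) - n1[, m]
      }
      mu_a_mat <- matrix(mu_a, K, M, byrow = TRUE)
      sig_a_mat <- matrix(sig_a, K, M, byrow = TRUE)
      al_new <- alpha + matrix(stats::rnorm(K * M, 0, s_a), K, M)
      ll <- function(al) {
        pp <- stats::plogis(al)
        n1 * log(pp) + n0 * log1p(-pp) +
          stats::dnorm(al, mu_a_mat, sig_a_mat, log = TRUE)
      }
      accv <- matrix(log(stats::runif(K * M)), K, M) < (ll(al_new) - ll(alpha))
      alpha[accv] <- al_new[accv]
      acc["a"] <- acc["a"] + mean(accv); n_prop["a"] <- n_prop["a"] + 1
    }

    ## occupancy coefficients, vectorized MH per taxon
    occ_ll <- function(b0, b1) {
      ps <- stats::plogis(outer(b0, rep(1, I)) + outer(b1, d_std))
      rowSums(z * log(ps) + (1 - z) * log1p(-ps))
    }
    b0_new <- beta0 + stats::rnorm(K, 0, s_b0)
    logr <- occ_ll(b0_new, beta1) - occ_ll(beta0, beta1) +
      stats::dnorm(b0_new, mu_b0, sig_b0, log = TRUE) -
      stats::dnorm(beta0, mu_b0, sig_b0, log = TRUE)
    accv <- log(stats::runif(K)) < logr
    beta0[accv] <- b0_new[accv]
    acc["b0"] <- acc["b0"] + mean(accv); n_prop["b0"] <- n_prop["b0"] + 1
    if (include_depth) {
      b1_new <- beta1 + stats::rnorm(K, 0, s_b1)
      logr <- occ_ll(beta0, b1_new) - occ_ll(beta0, beta1) +
        stats::dnorm(b1_new, mu_b1, sig_b1, log = TRUE) -
        stats::dnorm(beta1, mu_b1, sig_b1, log = TRUE)
      accv <- log(stats::runif(K)) < logr
      beta1[accv] <- b1_new[accv]
      acc["b1"] <- acc["b1"] + mean(accv); n_prop["b1"] <- n_prop["b1"] + 1
    }

    ## community hyperparameters
    mu_b0 <- update_mu(beta0, sig_b0)
    upd <- update_sigma(sig_b0, beta0, mu_b0)
    sig_b0 <- upd$sig
    acc["sig"] <- acc["sig"] + upd$acc; n_prop["sig"] <- n_prop["sig"] + 1
    if (include_depth) {
      mu_b1 <- update_mu(beta1, sig_b1)
      sig_b1 <- update_sigma(sig_b1, beta1, mu_b1)$sig
    }
    if (!theta_fixed) {
      mu_lt <- update_mu(ltheta, sig_lt)
      sig_lt <- update_sigma(sig_lt, ltheta, mu_lt)$sig
    }
    if (!p_fixed) {
      for (m in seq_len(M)) {
        mu_a[m] <- update_mu(alpha[, m], sig_a[m])
        sig_a[m] <- update_sigma(sig_a[m], alpha[, m], mu_a[m])$sig
      }
    }

    ## proposal-scale adaptation, burn-in only
    if (it <= burnin && it %% 50L == 0L) {
      tune <- function(s, rate) s * exp(0.5 * (rate - 0.35))
      if (n_prop["a"] > 0) s_a <- tune(s_a, acc["a"] / n_prop["a"])
      s_b0 <- tune(s_b0, acc["b0"] / n_prop["b0"])
      if (include_depth && n_prop["b1"] > 0) s_b1 <- tune(s_b1, acc["b1"] / n_prop["b1"])
      if (n_prop["lt"] > 0) s_lt <- tune(s_lt, acc["lt"] / n_prop["lt"])
      if (n_prop["sig"] > 0) s_sig <- tune(s_sig, acc["sig"] / n_prop["sig"])
      acc[] <- 0; n_prop[] <- 0
    }

    if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- c(beta0,
                      if (include_depth) beta1,
                      if (!theta_fixed) stats::plogis(ltheta),
                      if (!p_fixed) as.numeric(alpha),
                      mu_b0, sig_b0,
                      if (include_depth) c(mu_b1, sig_b1),
                      if (!theta_fixed) c(mu_lt, sig_lt),
                      if (!p_fixed) c(mu_a, sig_a))
    }
  }
  out[seq_len(row), , drop = FALSE]
}

#' Posterior of the community mean detection probability for a marker
#'
#' Per-draw inverse-logit transform of the marker's community detection
#' mean `mu_alpha[marker]`.
#'
#' @param fit An [fit_occupancy()] result.
#' @param marker Marker name (one of `fit$markers`).
#' @return List: `draws` (numeric vector on the probability scale, chains
#'   concatenated) and `summary` (one-row [summarize_posterior()] table).
#' @export
community_mean_detection <- function(fit, marker) {
  stopifnot(inherits(fit, "occupancy_fit"))
  if (!marker %in% fit$markers) {
    stop("community_mean_detection: unknown marker '", marker, "' (have: ",
         paste(fit$markers, collapse = ", "), ")")
  }
  par <- paste0("mu_alpha[", marker, "]")
  if (!par %in% colnames(fit$draws[[1L]])) {
    stop("community_mean_detection: detection was fixed in this fit")
  }
  chains <- lapply(fit$draws, function(d) {
    matrix(stats::plogis(d[, par]), ncol = 1L,
           dimnames = list(NULL, paste0("p_community[", marker, "]")))
  })
  list(draws = do.call(c, lapply(chains, as.numeric)),
       summary = summarize_posterior(chains))
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, median, central 95% interval, split
#' rank-normalized R-hat and effective sample size.
#'
#' @param draws An `occupancy_fit`, or a list of per-chain matrices
#'   (iterations x parameters, equal dimensions).
#' @return Data frame: `param`, `mean`, `median`, `q2.5`, `q97.5`, `rhat`,
#'   `ess`, `converged` (R-hat < 1.1). With a single chain R-hat is `NA`
#'   with a warning.
#' @export
summarize_posterior <- function(draws) {
  if (inherits(draws, "occupancy_fit")) draws <- draws$draws
  stopifnot(is.list(draws), length(draws) >= 1L)
  single <- length(draws) < 2L
  if (single) warning("summarize_posterior: single chain, R-hat unavailable")
  pars <- colnames(draws[[1L]])
  all_mat <- do.call(rbind, draws)
  rows <- lapply(pars, function(pn) {
    x <- all_mat[, pn]
    rh <- if (single) NA_real_ else rhat_split(lapply(draws, function(d) d[, pn]))
    ess <- tryCatch(
      sum(vapply(draws, function(d) as.numeric(coda::effectiveSize(d[, pn])),
                 numeric(1))),
      error = function(e) NA_real_)
    data.frame(param = pn, mean = mean(x), median = stats::median(x),
               q2.5 = stats::quantile(x, 0.025, names = FALSE),
               q97.5 = stats::quantile(x, 0.975, names = FALSE),
               rhat = rh, ess = ess,
               converged = !is.na(rh) && rh < 1.1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Split rank-normalized R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws of
#' split chains; the larger of the bulk value and the value on folded
#' (absolute-deviation-from-median) draws is returned. Constant chains
#' give `NA`.
#'
#' @param chains List of numeric vectors (one per chain, equal length).
#' @return R-hat (>= 1), or `NA` for degenerate input.
#' @export
rhat_split <- function(chains) {
  n <- min(lengths(chains))
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2L)
  split_chains <- unlist(lapply(chains, function(x) {
    x <- x[seq_len(2L * half)]
    list(x[seq_len(half)], x[half + seq_len(half)])
  }), recursive = FALSE)
  basic_rhat <- function(ch_list) {
    m <- length(ch_list); len <- length(ch_list[[1L]])
    means <- vapply(ch_list, mean, numeric(1))
    vars <- vapply(ch_list, stats::var, numeric(1))
    W <- mean(vars)
    B <- len * stats::var(means)
    if (W == 0) return(NA_real_)
    sqrt(((len - 1) / len * W + B / len) / W)
  }
  rank_norm <- function(ch_list) {
    all <- unlist(ch_list)
    if (diff(range(all)) == 0) return(NULL)
    S <- length(all)
    zv <- stats::qnorm((rank(all, ties.method = "average") - 3 / 8) / (S + 1 / 4))
    split(zv, rep(seq_along(ch_list), lengths(ch_list)))
  }
  zb <- rank_norm(split_chains)
  if (is.null(zb)) return(NA_real_)
  bulk <- basic_rhat(zb)
  folded <- rank_norm(lapply(split_chains, function(x) {
    abs(x - stats::median(unlist(split_chains)))
  }))
  tail_v <- if (is.null(folded)) NA_real_ else basic_rhat(folded)
  max(bulk, tail_v, na.rm = TRUE)
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Multi-species multi-scale occupancy fit\n")
  cat("dims: K =", x$dims["K"], "taxa, I =", x$dims["I"], "sites, J =",
      x$dims["J"], "replicates, M =", x$dims["M"], "markers\n")
  cat("chains:", x$mcmc["chains"], " iters:", x$mcmc["iters"],
      " burnin:", x$mcmc["burnin"], "\n")
  cat("converged (all R-hat < 1.1):", x$converged, "\n")
  mu_rows <- grep("^mu_", x$summary$param)
  print(x$summary[mu_rows, c("param", "mean", "q2.5", "q97.5", "rhat")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
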