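# Posterior inference by adaptive Metropolis-within-Gibbs. The AR(1)
# deviation processes are marginalised analytically: given the curve
# parameters, the logit-scale observations of one country and component
# are jointly multivariate normal with covariance sd^2 * rho^|t_i - t_j|
# plus the diagonal observation variances, so country-parameter updates
# need only small Cholesky solves. Latent annual trajectories are
# reconstructed afterwards by forward-filtering backward-sampling,
# vectorised across retained draws, and extended beyond the data period
# by sequential sampling from the AR(1) conditionals.

# ---- data preparation ------------------------------------------------

# Transformed observation terms grouped by country and component.
prepare_country_data <- function(obs, countries, bias_params, years,
                                 est_end) {
  dat <- setNames(vector("list", length(countries)), countries)
  for (code in countries) {
    rows <- which(obs$country_code == code)
    any_t <- list(z = numeric(), v = numeric(), tyr = numeric(),
                  iy = integer(), A = NULL)
    ratio_t <- list(z = numeric(), v = numeric(), tyr = numeric(),
                    iy = integer(), M = NULL)
    u_t <- list(z = numeric(), v = numeric(), tyr = numeric(), A = NULL)
    Aany <- Mrat <- Au <- NULL
    for (i in rows) {
      o <- as.list(obs[i, ])
      bl <- parse_flags(o$baseline_flags)
      mc <- parse_flags(o$misclass_flags)
      terms <- transformed_summaries(o, bias_params)
      iy <- max(min(floor(o$ref_year), est_end), years[1])
      arow <- as.numeric(BASELINE_FLAGS %in% bl)
      mrow <- as.numeric(MISCLASS_FLAGS %in% mc)
      for (term in terms) {
        v <- total_obs_variance(term, o$source_type, bias_params)
        if (term$which == "any") {
          any_t$z <- c(any_t$z, term$z); any_t$v <- c(any_t$v, v)
          any_t$tyr <- c(any_t$tyr, o$ref_year)
          any_t$iy <- c(any_t$iy, iy)
          Aany <- rbind(Aany, arow)
        } else if (term$which == "ratio") {
          ratio_t$z <- c(ratio_t$z, term$z); ratio_t$v <- c(ratio_t$v, v)
          ratio_t$tyr <- c(ratio_t$tyr, o$ref_year)
          ratio_t$iy <- c(ratio_t$iy, iy)
          Mrat <- rbind(Mrat, mrow)
        } else {
          u_t$z <- c(u_t$z, term$z); u_t$v <- c(u_t$v, v)
          u_t$tyr <- c(u_t$tyr, o$ref_year)
          Au <- rbind(Au, arow)
        }
      }
    }
    any_t$A <- Aany; ratio_t$M <- Mrat; u_t$A <- Au
    dat[[code]] <- list(
      any = if (length(any_t$z)) any_t else NULL,
      ratio = if (length(ratio_t$z)) ratio_t else NULL,
      u = if (length(u_t$z)) u_t else NULL
    )
  }
  dat
}

# systematic curve on the probability scale, clamped for logit
sys_curve <- function(t, la, lr, m) {
  p <- invlogit(la) / (1 + exp(-exp(lr) * (t - m)))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

# ---- tight-loop internals --------------------------------------------
# The sampler evaluates thousands of small likelihoods per second; the
# structures below keep everything static out of the inner loop.

LOG_SQRT_2PI <- 0.918938533204673

fast_sys <- function(t, la, lr, m) {
  p <- (1 / (1 + exp(-la))) / (1 + exp(-exp(lr) * (t - m)))
  p[p < 1e-12] <- 1e-12
  p[p > 1 - 1e-12] <- 1 - 1e-12
  p
}

# static per-country observation structures; the `cl` element is the
# positional list handed to the compiled likelihood
precompute_struct <- function(dat) {
  lapply(dat, function(d) {
    s <- list(a_n = 0L, r_n = 0L, u_n = 0L)
    a_t <- a_z <- r_t <- r_z <- u_t <- u_z <- u_iv <- numeric()
    r_i1 <- r_i2 <- r_i3 <- integer()
    u_cst <- 0
    if (!is.null(d$any)) {
      s$a_n <- length(d$any$z); a_t <- d$any$tyr; a_z <- d$any$z
      s$a_A <- d$any$A; s$a_v <- d$any$v
      s$a_D <- abs(outer(d$any$iy, d$any$iy, "-"))
    }
    if (!is.null(d$ratio)) {
      s$r_n <- length(d$ratio$z); r_t <- d$ratio$tyr; r_z <- d$ratio$z
      s$r_v <- d$ratio$v
      s$r_D <- abs(outer(d$ratio$iy, d$ratio$iy, "-"))
      r_i1 <- which(d$ratio$M[, 1] == 1) - 1L
      r_i2 <- which(d$ratio$M[, 2] == 1) - 1L
      r_i3 <- which(d$ratio$M[, 3] == 1) - 1L
    }
    if (!is.null(d$u)) {
      s$u_n <- length(d$u$z); u_t <- d$u$tyr; u_z <- d$u$z
      s$u_A <- d$u$A; u_iv <- 1 / d$u$v
      u_cst <- sum(-LOG_SQRT_2PI - 0.5 * log(d$u$v))
    }
    s$cl <- list(a_t, a_z, r_t, r_z, r_i1, r_i2, r_i3, u_t, u_z, u_iv,
                 u_cst)
    s
  })
}

# Inverses and log-determinant halves of the marginal covariances
# sd^2 * rho^|ti-tj| + diag(v); recomputed only when AR parameters move.
make_chol_cache <- function(pc, gnat) {
  C <- length(pc)
  Sia <- vector("list", C); Sir <- vector("list", C)
  lda <- numeric(C); ldr <- numeric(C)
  # stationary AR(1) variance: innovation variance / (1 - rho^2)
  q_a <- gnat[4]^2 / (1 - gnat[2]^2)
  q_r <- gnat[5]^2 / (1 - gnat[3]^2)
  for (i in seq_len(C)) {
    s <- pc[[i]]
    if (s$a_n) {
      R <- chol(q_a * gnat[2]^s$a_D + diag(s$a_v, s$a_n))
      Sia[[i]] <- chol2inv(R); lda[i] <- sum(log(diag(R)))
    }
    if (s$r_n) {
      R <- chol(q_r * gnat[3]^s$r_D + diag(s$r_v, s$r_n))
      Sir[[i]] <- chol2inv(R); ldr[i] <- sum(log(diag(R)))
    }
  }
  list(Ra = Sia, lda = lda, Rr = Sir, ldr = ldr)
}

# bias-shift contributions per country (change only in the bias block)
make_shift_cache <- function(pc, bnat) {
  sa <- lapply(pc, function(s) {
    if (s$a_n) as.vector(s$a_A %*% bnat[1:3]) else numeric()
  })
  su <- lapply(pc, function(s) {
    if (s$u_n) as.vector(s$u_A %*% bnat[4:6]) else numeric()
  })
  list(sa = sa, su = su)
}

# Observation log-likelihood of one country given its caches
# (compiled inner kernel).
loglik_fast <- function(s, th, slope, g1, g2, g3, Ra, lda, Rr, ldr,
                        sa, su) {
  cpp_country_loglik(s$cl, th, slope, g1, g2, g3, Ra, lda, Rr, ldr,
                     sa, su)
}

# ---- the sampler -----------------------------------------------------

#' Fit the hierarchical model to one marital group
#'
#' Adaptive random-walk Metropolis within Gibbs blocks: country transition
#' parameters (one block per country), hierarchy node means (conjugate
#' Gibbs), level standard deviations, global parameters (unmet-link slope
#' and AR(1) parameters, one joint block), and bias/misclassification
#' parameters (one joint block, when flagged observations exist). Married
#' and unmarried women are fitted separately; pass the group explicitly or
#' supply observations containing a single group. Countries without
#' observations are still sampled and receive their hierarchy-induced
#' prior. Trajectories are emitted on the full year grid; the segment
#' beyond the last data year is produced by [project()].
#'
#' @param observations `fp_observations` table.
#' @param demography `fp_demography` table (used for the year grid and
#'   downstream count operations).
#' @param meta `fp_meta` table.
#' @param model_cfg a [model_config()].
#' @param mcmc_cfg an [mcmc_config()].
#' @param marital_group `"married"` or `"unmarried"`; defaults to the
#'   single group present in `observations`.
#' @return object of class `fp_samples`: composition draw array
#'   `[draw, country, year, component]`, deviation draws, flat parameter
#'   draw matrix with chain ids, and the configuration fingerprint.
#' @export
fit <- function(observations, demography, meta, model_cfg = model_config(),
                mcmc_cfg = mcmc_config(), marital_group = NULL) {
  groups <- unique(observations$marital_group)
  if (is.null(marital_group)) {
    if (length(groups) > 1) {
      stop("observations contain both marital groups; fit them separately",
           call. = FALSE)
    }
    marital_group <- if (length(groups)) groups else "married"
  }
  obs <- observations[observations$marital_group == marital_group, ,
                      drop = FALSE]
  obs <- obs[obs$country_code %in% meta$country_code, , drop = FALSE]

  years <- model_cfg$years
  countries <- meta$country_code
  C <- length(countries)
  est_end <- if (nrow(obs)) {
    min(max(years), max(floor(obs$ref_year)))
  } else years[1]

  tree <- build_hierarchy(meta, marital_group, model_cfg$priors)
  bp <- model_cfg$bias_params
  dat <- prepare_country_data(obs, countries, bp, years, est_end)
  has_flags <- nrow(obs) > 0 &&
    any(nzchar(obs$baseline_flags) | nzchar(obs$misclass_flags))
  est_bias <- model_cfg$estimate_bias && has_flags

  # --- flat layout ----------------------------------------------------
  nd <- internal_nodes(tree)
  lv_nonroot <- setdiff(tree$levels, "world")
  theta_names <- as.vector(outer(PARAM_NAMES, countries,
                                 function(p, c) paste0("theta.", c, ".", p)))
  mu_names <- as.vector(outer(PARAM_NAMES, nd$id,
                              function(p, n) paste0("mu.", n, ".", p)))
  sig_names <- as.vector(outer(PARAM_NAMES, lv_nonroot,
                               function(p, l) paste0("sigma.", l, ".", p)))
  flat_names <- c(theta_names, mu_names, sig_names, GLOBAL_NAMES,
                  BIAS_PAR_NAMES)

  fixed <- model_cfg$fixed
  if (length(fixed) && !all(names(fixed) %in% flat_names)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), flat_names), collapse = ", "),
         call. = FALSE)
  }

  pr <- tree$priors
  rho_max <- model_cfg$rho_max
  sp <- model_cfg$slope_prior

  # children bookkeeping for the Gibbs updates
  node_children <- lapply(nd$id, function(id) {
    kid_rows <- which(tree$nodes$parent == id)
    kids <- tree$nodes$id[kid_rows]
    lv <- unique(tree$nodes$level[kid_rows])
    if (length(lv) > 1) stop("mixed child levels under ", id)
    if (lv == "country") {
      list(type = "theta", idx = match(sub("^c:", "", kids), countries),
           level = "country")
    } else {
      list(type = "mu", idx = match(kids, nd$id), level = lv)
    }
  })
  names(node_children) <- nd$id
  parent_mu_row <- match(tree$nodes$parent[match(nd$id, tree$nodes$id)],
                         nd$id)  # NA for world
  country_parent_row <- match(tree$country_parent, nd$id)
  node_level <- nd$level

  # residual sets per (non-root) level, for the sd updates
  level_members <- lapply(lv_nonroot, function(lv) {
    if (lv == "country") {
      list(type = "theta", idx = seq_len(C), parent = country_parent_row)
    } else {
      i <- which(node_level == lv)
      list(type = "mu", idx = i, parent = parent_mu_row[i])
    }
  })
  names(level_members) <- lv_nonroot

  # --- fixed-value masks ----------------------------------------------
  take_fixed <- function(names_vec) {
    v <- rep(NA_real_, length(names_vec))
    hit <- names_vec %in% names(fixed)
    v[hit] <- fixed[names_vec[hit]]
    v
  }
  theta_fix <- matrix(take_fixed(theta_names), nrow = C, byrow = TRUE,
                      dimnames = list(countries, PARAM_NAMES))
  mu_fix <- matrix(take_fixed(mu_names), nrow = nrow(nd), byrow = TRUE,
                   dimnames = list(nd$id, PARAM_NAMES))
  sig_fix <- matrix(take_fixed(sig_names), nrow = length(lv_nonroot),
                    byrow = TRUE, dimnames = list(lv_nonroot, PARAM_NAMES))
  glob_fix <- take_fixed(GLOBAL_NAMES)          # natural scale
  bias_fix <- take_fixed(BIAS_PAR_NAMES)        # natural scale

  glob_to_raw <- function(gn) {
    c(gn[1], logit(pmin(pmax(gn[2:3] / rho_max, 1e-10), 1 - 1e-10)),
      log(pmax(gn[4:5], 1e-10)))
  }
  raw_to_glob <- function(gr) {
    c(gr[1], rho_max * invlogit(gr[2:3]), exp(gr[4:5]))
  }
  bias_to_raw <- function(bn) {
    c(bn[1:6], logit(pmin(pmax(bn[7:9], 1e-10), 1 - 1e-10)))
  }
  raw_to_bias <- function(br) c(br[1:6], invlogit(br[7:9]))

  glob_prior <- function(gr) {
    # slope: normal; rho: uniform(0, rho_max) via logit transform
    # (jacobian); sd: half-normal via log transform (jacobian)
    s <- invlogit(gr[2:3])
    sum(stats::dnorm(gr[1], sp[["mean"]], sp[["sd"]], log = TRUE)) +
      sum(log(s) + log1p(-s)) +
      sum(dhalfnorm_log(exp(gr[4:5]), model_cfg$ar_sd_hn_scale) + gr[4:5])
  }
  bias_prior <- function(br) {
    sum(stats::dnorm(br[1:6], 0, model_cfg$shift_prior_sd, log = TRUE)) +
      sum(stats::dnorm(br[7:9], 0, model_cfg$misclass_prior_sd, log = TRUE))
  }

  # --- per-chain sampler ----------------------------------------------
  n_iter <- mcmc_cfg$n_iterations
  n_warm <- mcmc_cfg$n_warmup
  thin <- mcmc_cfg$thinning
  keep_iters <- seq(n_warm + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  if (n_keep < 1) stop("no draws retained; check thinning", call. = FALSE)

  base_step_theta <- c(0.15, 0.15, 3, 0.15, 0.15, 3, 0.2)
  pc <- precompute_struct(dat)
  config_bias_nat <- c(bp$shift_any[BASELINE_FLAGS],
                       bp$shift_u[BASELINE_FLAGS],
                       bp$misclass_realloc[MISCLASS_FLAGS])

  run_chain <- function(chain_id) {
    set.seed(derive_seed(mcmc_cfg$seed, paste0(marital_group, ".chain",
                                               chain_id)))
    # initial state: hyperparameters at prior medians, country
    # parameters at their hierarchy means, deviations at zero
    theta <- matrix(rep(pr$root_mean, each = C), nrow = C,
                    dimnames = list(countries, PARAM_NAMES))
    mu <- matrix(rep(pr$root_mean, each = nrow(nd)), nrow = nrow(nd),
                 dimnames = list(nd$id, PARAM_NAMES))
    sig <- pr$hn_scale[lv_nonroot, , drop = FALSE] * stats::qnorm(0.75)
    glob_raw <- glob_to_raw(c(sp[["mean"]], rho_max / 2, rho_max / 2,
                              rep(model_cfg$ar_sd_hn_scale *
                                    stats::qnorm(0.75), 2)))
    bias_raw <- if (est_bias) bias_to_raw(c(rep(0, 6), rep(0.5, 3)))
                else bias_to_raw(config_bias_nat)
    # apply fixed values
    theta[!is.na(theta_fix)] <- theta_fix[!is.na(theta_fix)]
    mu[!is.na(mu_fix)] <- mu_fix[!is.na(mu_fix)]
    sig[!is.na(sig_fix)] <- sig_fix[!is.na(sig_fix)]
    glob_raw[!is.na(glob_fix)] <- glob_to_raw(
      ifelse(is.na(glob_fix), raw_to_glob(glob_raw), glob_fix))[
        !is.na(glob_fix)]
    bias_raw[!is.na(bias_fix)] <- bias_to_raw(
      ifelse(is.na(bias_fix), raw_to_bias(bias_raw), bias_fix))[
        !is.na(bias_fix)]

    bias_free <- which(is.na(bias_fix))
    theta_free <- lapply(seq_len(C),
                         function(i) which(is.na(theta_fix[i, ])))

    gnat <- raw_to_glob(glob_raw)
    bnat <- raw_to_bias(bias_raw)
    chc <- make_chol_cache(pc, gnat)
    shc <- make_shift_cache(pc, bnat)
    cll <- numeric(C)
    for (i in seq_len(C)) {
      cll[i] <- loglik_fast(pc[[i]], theta[i, ], gnat[1], bnat[7],
                            bnat[8], bnat[9], chc$Ra[[i]], chc$lda[i],
                            chc$Rr[[i]], chc$ldr[i], shc$sa[[i]],
                            shc$su[[i]])
    }
    if (any(!is.finite(cll))) {
      stop("non-finite log-posterior at initialization for country ",
           countries[which(!is.finite(cll))[1]], call. = FALSE)
    }

    # adaptation state: scalar log step scales (Robbins-Monro towards
    # the target acceptance rate) plus Haario-style running covariances
    # for the country and global blocks, with the proposal Cholesky
    # refreshed in batches during warmup and frozen afterwards
    ls_theta <- numeric(C)
    ls_sig <- matrix(0, length(lv_nonroot), 7,
                     dimnames = list(lv_nonroot, PARAM_NAMES))
    ls_glob <- 0; ls_bias <- 0; ls_shift <- 0
    tgt <- mcmc_cfg$target_accept
    # translation move applies only to parameters with no fixed values
    # anywhere in their stack
    shift_ok <- vapply(seq_len(7), function(p) {
      !any(!is.na(theta_fix[, p])) && !any(!is.na(mu_fix[, p]))
    }, logical(1))
    base_shift <- c(0.3, 0.15, 4, 0.3, 0.15, 4, 0.3)
    cov_start <- 200L      # draws before covariance proposals kick in
    cov_refresh <- 50L
    th_cnt <- 0
    th_mean <- matrix(0, C, 7)
    th_M2 <- array(0, c(C, 7, 7))
    th_L <- vector("list", C)    # chol of scaled covariance, free subset
    gl_mean <- numeric(5); gl_M2 <- matrix(0, 5, 5); gl_L <- NULL
    glob_free <- which(is.na(glob_fix))

    out <- matrix(NA_real_, n_keep, length(flat_names),
                  dimnames = list(NULL, flat_names))
    k_out <- 0

    for (iter in seq_len(n_iter)) {
      adapting <- iter <= n_warm
      gam <- if (adapting) min(0.25, 2 / sqrt(iter)) else 0

      # 1. country parameter blocks (joint 7-d proposal; covariance
      # learned during warmup captures the asymptote/rate/midpoint
      # correlation of the logistic curves)
      for (i in seq_len(C)) {
        free <- theta_free[[i]]
        if (!length(free)) next
        pm <- mu[country_parent_row[i], ]
        prop <- theta[i, ]
        z <- stats::rnorm(length(free))
        if (is.null(th_L[[i]]) || stats::runif(1) < 0.1) {
          prop[free] <- prop[free] + exp(ls_theta[i]) *
            base_step_theta[free] * z
        } else {
          prop[free] <- prop[free] + exp(ls_theta[i]) *
            drop(crossprod(th_L[[i]], z))
        }
        lp_cur <- cll[i] +
          sum(stats::dnorm(theta[i, free], pm[free],
                           sig["country", free], log = TRUE))
        ll_prop <- loglik_fast(pc[[i]], prop, gnat[1], bnat[7], bnat[8],
                               bnat[9], chc$Ra[[i]], chc$lda[i],
                               chc$Rr[[i]], chc$ldr[i], shc$sa[[i]],
                               shc$su[[i]])
        lp_prop <- ll_prop +
          sum(stats::dnorm(prop[free], pm[free], sig["country", free],
                           log = TRUE))
        acc <- is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp_cur
        if (acc) { theta[i, ] <- prop; cll[i] <- ll_prop }
        ls_theta[i] <- ls_theta[i] + gam * ((if (acc) 1 else 0) - tgt)
      }

      # 2. node means: conjugate normal Gibbs, leaves upward
      for (n_i in rev(seq_len(nrow(nd)))) {
        ch <- node_children[[n_i]]
        X <- if (ch$type == "theta") theta[ch$idx, , drop = FALSE]
             else mu[ch$idx, , drop = FALSE]
        sd_child <- sig[ch$level, ]
        if (is.na(parent_mu_row[n_i])) {
          pm <- pr$root_mean; ps <- pr$root_sd
        } else {
          pm <- mu[parent_mu_row[n_i], ]
          ps <- sig[node_level[n_i], ]
        }
        prec <- nrow(X) / sd_child^2 + 1 / ps^2
        mean_post <- (colSums(X) / sd_child^2 + pm / ps^2) / prec
        draw <- stats::rnorm(7, mean_post, 1 / sqrt(prec))
        fx <- !is.na(mu_fix[n_i, ])
        draw[fx] <- mu_fix[n_i, fx]
        mu[n_i, ] <- draw
      }

      # 2b. translation move: shift one parameter's whole stack (root
      # mean, node means, country values) by the same amount. The
      # child-given-parent residuals are invariant, so only the root
      # prior and the data likelihood enter the ratio. Without this the
      # hierarchy translates by a slow random walk (funnel behaviour).
      if (any(shift_ok)) {
        delta <- numeric(7)
        delta[shift_ok] <- exp(ls_shift) * base_shift[shift_ok] *
          stats::rnorm(sum(shift_ok))
        th_prop <- sweep(theta, 2, delta, "+")
        pll <- numeric(C)
        for (i in seq_len(C)) {
          pll[i] <- loglik_fast(pc[[i]], th_prop[i, ], gnat[1], bnat[7],
                                bnat[8], bnat[9], chc$Ra[[i]],
                                chc$lda[i], chc$Rr[[i]], chc$ldr[i],
                                shc$sa[[i]], shc$su[[i]])
        }
        w_old <- mu["world", ]; w_new <- w_old + delta
        lp_cur <- sum(cll) +
          sum(stats::dnorm(w_old[shift_ok], pr$root_mean[shift_ok],
                           pr$root_sd[shift_ok], log = TRUE))
        lp_prop <- sum(pll) +
          sum(stats::dnorm(w_new[shift_ok], pr$root_mean[shift_ok],
                           pr$root_sd[shift_ok], log = TRUE))
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
        if (acc) {
          theta <- th_prop
          mu <- sweep(mu, 2, delta, "+")
          cll <- pll
        }
        ls_shift <- ls_shift + gam * ((if (acc) 1 else 0) - tgt)
      }

      # 3. level standard deviations
      for (lv in lv_nonroot) {
        mem <- level_members[[lv]]
        vals <- if (mem$type == "theta") theta[mem$idx, , drop = FALSE]
                else mu[mem$idx, , drop = FALSE]
        pars <- mu[mem$parent, , drop = FALSE]
        res <- vals - pars
        for (p in seq_len(7)) {
          if (!is.na(sig_fix[lv, p])) next
          cur <- sig[lv, p]
          prop <- cur * exp(exp(ls_sig[lv, p]) * 0.3 * stats::rnorm(1))
          lp_cur <- sum(stats::dnorm(res[, p], 0, cur, log = TRUE)) +
            dhalfnorm_log(cur, pr$hn_scale[lv, p]) + log(cur)
          lp_prop <- sum(stats::dnorm(res[, p], 0, prop, log = TRUE)) +
            dhalfnorm_log(prop, pr$hn_scale[lv, p]) + log(prop)
          acc <- is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp_cur
          if (acc) sig[lv, p] <- prop
          ls_sig[lv, p] <- ls_sig[lv, p] + gam * ((if (acc) 1 else 0) - tgt)
        }
      }

      # 4. global block: slope + AR parameters, one joint proposal with
      # learned covariance (full-likelihood evaluation; covariance
      # caches rebuilt because the AR parameters move)
      if (length(glob_free)) {
        step_glob <- c(0.1, 0.3, 0.3, 0.2, 0.2)
        prop_raw <- glob_raw
        z <- stats::rnorm(length(glob_free))
        if (is.null(gl_L)) {
          prop_raw[glob_free] <- prop_raw[glob_free] + exp(ls_glob) *
            step_glob[glob_free] * z
        } else {
          prop_raw[glob_free] <- prop_raw[glob_free] + exp(ls_glob) *
            drop(crossprod(gl_L, z))
        }
        pnat <- raw_to_glob(prop_raw)
        pchc <- make_chol_cache(pc, pnat)
        pll <- numeric(C)
        for (i in seq_len(C)) {
          pll[i] <- loglik_fast(pc[[i]], theta[i, ], pnat[1], bnat[7],
                                bnat[8], bnat[9], pchc$Ra[[i]],
                                pchc$lda[i], pchc$Rr[[i]], pchc$ldr[i],
                                shc$sa[[i]], shc$su[[i]])
        }
        lp_cur <- sum(cll) + glob_prior(glob_raw)
        lp_prop <- sum(pll) + glob_prior(prop_raw)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
        if (acc) {
          glob_raw <- prop_raw; gnat <- pnat; chc <- pchc; cll <- pll
        }
        ls_glob <- ls_glob + gam * ((if (acc) 1 else 0) - tgt)
      }

      # 5. bias/misclassification block (means only; chols unchanged)
      if (est_bias && length(bias_free)) {
        prop_raw <- bias_raw
        prop_raw[bias_free] <- prop_raw[bias_free] + exp(ls_bias) *
          0.1 * stats::rnorm(length(bias_free))
        pb <- raw_to_bias(prop_raw)
        pshc <- make_shift_cache(pc, pb)
        pll <- numeric(C)
        for (i in seq_len(C)) {
          pll[i] <- loglik_fast(pc[[i]], theta[i, ], gnat[1], pb[7],
                                pb[8], pb[9], chc$Ra[[i]], chc$lda[i],
                                chc$Rr[[i]], chc$ldr[i], pshc$sa[[i]],
                                pshc$su[[i]])
        }
        lp_cur <- sum(cll) + bias_prior(bias_raw)
        lp_prop <- sum(pll) + bias_prior(prop_raw)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
        if (acc) { bias_raw <- prop_raw; bnat <- pb; shc <- pshc; cll <- pll }
        ls_bias <- ls_bias + gam * ((if (acc) 1 else 0) - tgt)
      }

      # covariance learning (warmup only); the accumulators restart at
      # mid-warmup so the initial transient does not pollute the
      # learned covariance
      if (adapting) {
        if (iter == n_warm %/% 2) {
          th_cnt <- 0
          th_mean[] <- 0; th_M2[] <- 0
          gl_mean[] <- 0; gl_M2[] <- 0
        }
        th_cnt <- th_cnt + 1
        d_th <- theta - th_mean
        th_mean <- th_mean + d_th / th_cnt
        for (i in seq_len(C)) {
          th_M2[i, , ] <- th_M2[i, , ] +
            tcrossprod(d_th[i, ], theta[i, ] - th_mean[i, ])
        }
        d_gl <- glob_raw - gl_mean
        gl_mean <- gl_mean + d_gl / th_cnt
        gl_M2 <- gl_M2 + tcrossprod(d_gl, glob_raw - gl_mean)
        if (th_cnt >= cov_start && th_cnt %% cov_refresh == 0) {
          for (i in seq_len(C)) {
            free <- theta_free[[i]]
            if (length(free) < 2) next
            S <- th_M2[i, free, free] / (th_cnt - 1)
            S <- 2.38^2 / length(free) *
              (S + diag(1e-8, length(free)))
            L <- tryCatch(chol(S), error = function(e) NULL)
            if (!is.null(L)) th_L[[i]] <- L
          }
          if (length(glob_free) >= 2) {
            S <- gl_M2[glob_free, glob_free] / (th_cnt - 1)
            S <- 2.38^2 / length(glob_free) *
              (S + diag(1e-8, length(glob_free)))
            gl_L <- tryCatch(chol(S), error = function(e) gl_L)
          }
        }
      }

      if (iter > n_warm && (iter - n_warm) %% thin == 0) {
        k_out <- k_out + 1
        out[k_out, ] <- c(t(theta), t(mu), t(sig), raw_to_glob(glob_raw),
                          raw_to_bias(bias_raw))
      }
    }
    out
  }

  chains <- lapply(seq_len(mcmc_cfg$n_chains), run_chain)
  params <- do.call(rbind, chains)
  chain_id <- rep(seq_len(mcmc_cfg$n_chains), each = n_keep)

  smp <- structure(list(
    params = params, chain = chain_id, n_chains = mcmc_cfg$n_chains,
    marital_group = marital_group, countries = countries,
    years = years[years <= est_end], full_years = years,
    est_end = est_end, dat = dat, seed = mcmc_cfg$seed,
    model_cfg = model_cfg, mcmc_cfg = mcmc_cfg,
    fingerprint = list(seed = mcmc_cfg$seed, n_chains = mcmc_cfg$n_chains,
                       n_iterations = n_iter, n_warmup = n_warm,
                       thinning = thin, marital_group = marital_group,
                       n_countries = C, n_obs = nrow(obs))
  ), class = "fp_samples")

  smp <- reconstruct_trajectories(smp)
  if (max(years) > est_end) smp <- project(smp, max(years))
  smp
}

# ---- trajectory reconstruction ---------------------------------------

# Per-draw mean of the transformed observations of one country/component.
draw_means <- function(params, code, comp, d, marital_dummy = NULL) {
  th <- function(p) params[, paste0("theta.", code, ".", p)]
  if (comp == "any") {
    M <- sapply(seq_along(d$tyr), function(j) {
      logit(sys_curve(d$tyr[j], th("la_any"), th("lr_any"), th("m_any")))
    })
    if (length(d$tyr) == 1) M <- matrix(M, ncol = 1)
    shift <- d$A %*% rbind(params[, "shift_any.age_truncated"],
                           params[, "shift_any.geographic_subset"],
                           params[, "shift_any.other_nonbaseline"])
    M + t(shift)
  } else {
    g <- cbind(params[, "misclass.modern_inflated"],
               params[, "misclass.traditional_inflated"],
               params[, "misclass.methods_combined"])
    M <- sapply(seq_along(d$tyr), function(j) {
      r <- sys_curve(d$tyr[j], th("la_ratio"), th("lr_ratio"),
                     th("m_ratio"))
      if (!is.null(d$M)) {
        if (d$M[j, 1] == 1) r <- r + g[, 1] * (1 - r)
        if (d$M[j, 2] == 1) r <- r * (1 - g[, 2])
        if (d$M[j, 3] == 1) r <- r + g[, 3] * (1 - r)
      }
      logit(pmin(pmax(r, 1e-12), 1 - 1e-12))
    })
    if (length(d$tyr) == 1) M <- matrix(M, ncol = 1)
    M
  }
}

# FFBS for the AR(1) deviations of one country/component, vectorised over
# draws. resid: draws x n_obs residual matrix; iy: grid year of each
# observation; v: observation variances; rho, q: per-draw vectors
# (q = sd^2). Returns draws x T matrix.
ffbs_ar1 <- function(resid, iy, v, rho, q, years_est) {
  T_len <- length(years_est)
  n_draws <- length(rho)
  # pool observations sharing a grid year
  obs_by_year <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    j <- which(iy == years_est[t])
    if (length(j)) {
      P <- sum(1 / v[j])
      ybar <- if (length(j) == 1) resid[, j] else
        as.vector(resid[, j, drop = FALSE] %*% (1 / v[j])) / P
      obs_by_year[[t]] <- list(ybar = ybar, vbar = 1 / P)
    }
  }
  m <- matrix(0, n_draws, T_len)
  Cf <- matrix(0, n_draws, T_len)
  a <- numeric(n_draws); R <- q / (1 - rho^2)
  for (t in seq_len(T_len)) {
    if (t > 1) { a <- rho * m[, t - 1]; R <- rho^2 * Cf[, t - 1] + q }
    ob <- obs_by_year[[t]]
    if (is.null(ob)) {
      m[, t] <- a; Cf[, t] <- R
    } else {
      K <- R / (R + ob$vbar)
      m[, t] <- a + K * (ob$ybar - a)
      Cf[, t] <- (1 - K) * R
    }
  }
  x <- matrix(0, n_draws, T_len)
  x[, T_len] <- stats::rnorm(n_draws, m[, T_len],
                             sqrt(pmax(Cf[, T_len], 0)))
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      denom <- rho^2 * Cf[, t] + q
      J <- ifelse(denom > 0, rho * Cf[, t] / denom, 0)
      mean_t <- m[, t] + J * (x[, t + 1] - rho * m[, t])
      var_t <- pmax(Cf[, t] - J * rho * Cf[, t], 0)
      x[, t] <- stats::rnorm(n_draws, mean_t, sqrt(var_t))
    }
  }
  x
}

# Systematic curves for all draws of one country over a year vector.
sys_matrix <- function(params, code, years_vec, comp) {
  pfx <- if (comp == "any") c("la_any", "lr_any", "m_any")
         else c("la_ratio", "lr_ratio", "m_ratio")
  la <- params[, paste0("theta.", code, ".", pfx[1])]
  lr <- params[, paste0("theta.", code, ".", pfx[2])]
  m <- params[, paste0("theta.", code, ".", pfx[3])]
  out <- matrix(0, nrow(params), length(years_vec))
  for (j in seq_along(years_vec)) {
    out[, j] <- sys_curve(years_vec[j], la, lr, m)
  }
  out
}

compose_from_dev <- function(smp, code, dev_any, dev_ratio, years_vec) {
  params <- smp$params
  p_any <- invlogit(logit(sys_matrix(params, code, years_vec, "any")) +
                      dev_any)
  r_mod <- invlogit(logit(sys_matrix(params, code, years_vec, "ratio")) +
                      dev_ratio)
  u_int <- params[, paste0("theta.", code, ".u_int")]
  u <- invlogit(u_int + params[, "slope"] * p_any)
  list(modern = p_any * r_mod, traditional = p_any * (1 - r_mod),
       unmet = (1 - p_any) * u, no_need = (1 - p_any) * (1 - u))
}

# Build the composition and deviation arrays on the estimation grid.
reconstruct_trajectories <- function(smp) {
  set.seed(derive_seed(smp$seed, paste0(smp$marital_group, ".traj")))
  params <- smp$params
  years_est <- smp$years
  C <- length(smp$countries)
  n_draws <- nrow(params)
  T_len <- length(years_est)
  comp_names <- c("modern", "traditional", "unmet", "no_need")
  comp <- array(NA_real_, c(n_draws, C, T_len, 4),
                dimnames = list(NULL, smp$countries, years_est,
                                comp_names))
  dev <- array(NA_real_, c(n_draws, C, T_len, 2),
               dimnames = list(NULL, smp$countries, years_est,
                               c("any", "ratio")))
  for (i in seq_len(C)) {
    code <- smp$countries[i]
    d <- smp$dat[[code]]
    for (cm in c("any", "ratio")) {
      rho <- params[, paste0("rho_", cm)]
      q <- params[, paste0("sd_", cm)]^2
      dcomp <- d[[cm]]
      if (is.null(dcomp)) {
        # no data: unconditional stationary path
        x <- matrix(0, n_draws, T_len)
        x[, 1] <- stats::rnorm(n_draws, 0, sqrt(q / (1 - rho^2)))
        if (T_len > 1) {
          for (t in 2:T_len) {
            x[, t] <- rho * x[, t - 1] + stats::rnorm(n_draws, 0, sqrt(q))
          }
        }
      } else {
        resid <- matrix(rep(dcomp$z, each = n_draws), n_draws) -
          draw_means(params, code, cm, dcomp)
        x <- ffbs_ar1(resid, dcomp$iy, dcomp$v, rho, q, years_est)
      }
      dev[, i, , if (cm == "any") 1 else 2] <- x
    }
    cc <- compose_from_dev(smp, code, dev[, i, , 1], dev[, i, , 2],
                           years_est)
    for (k in seq_along(comp_names)) comp[, i, , k] <- cc[[comp_names[k]]]
  }
  smp$comp <- comp
  smp$dev <- dev
  smp
}

#' Project trajectories beyond the data period
#'
#' The systematic trend parameters are time-invariant, so the curves are
#' evaluated directly at future years; the AR(1) deviations are continued
#' forward by sequentially sampling from their conditional distributions
#' given the last estimated value, using each draw's own (rho, sd). Any
#' previously projected segment is re-drawn.
#'
#' @param smp an `fp_samples` object.
#' @param horizon_end last projection year (<= the configured grid end).
#' @return the extended `fp_samples` object.
#' @export
project <- function(smp, horizon_end) {
  if (horizon_end < smp$est_end) {
    stop("projection horizon precedes the last data year (",
         smp$est_end, ")", call. = FALSE)
  }
  if (horizon_end > max(smp$full_years)) {
    stop("horizon beyond the configured year grid", call. = FALSE)
  }
  set.seed(derive_seed(smp$seed, paste0(smp$marital_group, ".project",
                                        horizon_end)))
  years_est <- smp$full_years[smp$full_years <= smp$est_end]
  new_years <- smp$full_years[smp$full_years > smp$est_end &
                                smp$full_years <= horizon_end]
  # truncate to the estimation segment
  keep <- seq_along(years_est)
  comp <- smp$comp[, , keep, , drop = FALSE]
  dev <- smp$dev[, , keep, , drop = FALSE]
  if (!length(new_years)) {
    smp$comp <- comp; smp$dev <- dev; smp$years <- years_est
    return(smp)
  }
  params <- smp$params
  n_draws <- nrow(params)
  C <- length(smp$countries)
  Tn <- length(new_years)
  comp_ext <- array(NA_real_, c(n_draws, C, Tn, 4),
                    dimnames = list(NULL, smp$countries, new_years,
                                    dimnames(comp)[[4]]))
  dev_ext <- array(NA_real_, c(n_draws, C, Tn, 2),
                   dimnames = list(NULL, smp$countries, new_years,
                                   c("any", "ratio")))
  for (i in seq_len(C)) {
    code <- smp$countries[i]
    for (cm in c("any", "ratio")) {
      k <- if (cm == "any") 1 else 2
      rho <- params[, paste0("rho_", cm)]
      sdv <- params[, paste0("sd_", cm)]
      last <- dev[, i, length(years_est), k]
      x <- matrix(0, n_draws, Tn)
      prev <- last
      for (t in seq_len(Tn)) {
        prev <- rho * prev + stats::rnorm(n_draws, 0, sdv)
        x[, t] <- prev
      }
      dev_ext[, i, , k] <- x
    }
    cc <- compose_from_dev(smp, code, dev_ext[, i, , 1, drop = TRUE],
                           dev_ext[, i, , 2, drop = TRUE], new_years)
    for (k in seq_len(4)) {
      comp_ext[, i, , k] <- cc[[dimnames(comp)[[4]][k]]]
    }
  }
  smp$comp <- abind_years(comp, comp_ext)
  smp$dev <- abind_years(dev, dev_ext)
  smp$years <- c(years_est, new_years)
  smp
}

# bind two [draw, country, year, comp] arrays along the year axis
abind_years <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(NA_real_, c(da[1], da[2], da[3] + db[3], da[4]),
               dimnames = list(NULL, dimnames(a)[[2]],
                               c(dimnames(a)[[3]], dimnames(b)[[3]]),
                               dimnames(a)[[4]]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' @export
print.fp_samples <- function(x, ...) {
  cat("fp_samples:", x$marital_group, "women;",
      length(x$countries), "countries;",
      nrow(x$params), "draws from", x$n_chains, "chains;",
      "years", min(x$years), "-", max(x$years),
      "(data through", paste0(x$est_end, ")\n"))
  invisible(x)
}
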