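#' Parameters for the EPIC-like methylation simulator
#'
#' Desk-scale stand-in for Infinium intensity data: probes x samples
#' methylated/unmethylated signals whose implied beta values carry a planted
#' baseline mixture (unmethylated / intermediate / methylated components)
#' plus signed differential effects at chosen probes.
#'
#' @param n_probes Number of probes.
#' @param n_pairs Number of primary/metastasis pairs (paired design). Set to
#'   `NULL` and give `n_per_group` for a two-group design.
#' @param n_per_group Samples per group for the unpaired design.
#' @param baseline_means,baseline_sds,baseline_weights Mixture describing
#'   the baseline beta distribution.
#' @param n_dm Number of planted differential probes.
#' @param delta_beta Signed planted effect(s), recycled across the `n_dm`
#'   probes; positive means hypermethylated in the first-named group.
#' @param noise_sd Per-observation beta noise SD.
#' @param probe_type_fraction_II Fraction of type II probes.
#' @param type2_attenuation Compression of type II betas toward 0.5
#'   (0 = none), emulating the design bias that normalisation corrects.
#' @param detection_fail_rate Rate of injected detection failures.
#' @param intensity_scale Mean total intensity (M + U).
#' @param group_labels Two labels, first is the "A" group carrying the
#'   planted effect (default metastasis "LM" versus primary "P").
#' @param seed Integer seed.
#' @return A list of class `meth_sim_params`.
#' @export
meth_sim_params <- function(n_probes = 10000, n_pairs = 6, n_per_group = NULL,
                            baseline_means = c(0.1, 0.5, 0.85),
                            baseline_sds = c(0.05, 0.1, 0.08),
                            baseline_weights = c(0.45, 0.15, 0.4),
                            n_dm = 50, delta_beta = 0.4, noise_sd = 0.05,
                            probe_type_fraction_II = 0.84,
                            type2_attenuation = 0,
                            detection_fail_rate = 0,
                            intensity_scale = 10000,
                            group_labels = c("LM", "P"), seed = 1L) {
  if (n_dm > n_probes) {
    abort("`n_dm` cannot exceed `n_probes`.", class = "itf_parameter_error")
  }
  if (is.null(n_pairs) && is.null(n_per_group)) {
    abort("Give `n_pairs` (paired) or `n_per_group` (two-group).",
          class = "itf_parameter_error")
  }
  stop_if_not_fraction(probe_type_fraction_II, "probe_type_fraction_II")
  stop_if_not_fraction(detection_fail_rate, "detection_fail_rate")
  structure(list(n_probes = as.integer(n_probes),
                 n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
                 n_per_group = if (!is.null(n_per_group))
                   as.integer(n_per_group),
                 baseline_means = baseline_means, baseline_sds = baseline_sds,
                 baseline_weights = baseline_weights,
                 n_dm = as.integer(n_dm), delta_beta = delta_beta,
                 noise_sd = noise_sd,
                 probe_type_fraction_II = probe_type_fraction_II,
                 type2_attenuation = type2_attenuation,
                 detection_fail_rate = detection_fail_rate,
                 intensity_scale = intensity_scale,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "meth_sim_params")
}

#' Simulate methylated/unmethylated intensity matrices with planted effects
#'
#' Per observation, a true beta is drawn from the baseline mixture, shifted
#' by the planted signed effect in the first group, perturbed by
#' `Normal(0, noise_sd)` and clamped inside (0, 1); total intensity is a
#' scaled Gamma draw split as `M = T * beta`, `U = T * (1 - beta)`, so the
#' implied `M / (M + U)` equals the noisy beta exactly and all intensities
#' are strictly positive. Detection failures are injected at the stated rate.
#'
#' @param params A [meth_sim_params()] object.
#' @return A list of class `meth_sim` with matrices `M`, `U`, `detection_p`
#'   (probes x samples), `samples` (tibble: `sample`, `group`, `pair_id`),
#'   `probes` (tibble: `probe_id`, `probe_type`), and `truth` (tibble of
#'   planted probes: `probe_id`, `delta_beta`, `base_beta`).
#' @export
simulate_methylation <- function(params) {
  if (!inherits(params, "meth_sim_params")) {
    abort("`params` must come from meth_sim_params().",
          class = "itf_parameter_error")
  }
  paired <- !is.null(params$n_pairs)
  n_a <- if (paired) params$n_pairs else params$n_per_group
  n_b <- n_a
  gl <- params$group_labels
  p <- params$n_probes

  withr::with_seed(params$seed, {
    comp <- sample.int(length(params$baseline_means), p, replace = TRUE,
                       prob = params$baseline_weights)
    base <- rnorm(p, params$baseline_means[comp], params$baseline_sds[comp])
    base <- pmin(pmax(base, 0.02), 0.98)

    dm_idx <- if (params$n_dm > 0) sort(sample.int(p, params$n_dm)) else
      integer()
    delta <- numeric(p)
    if (params$n_dm > 0) {
      d <- rep_len(params$delta_beta, params$n_dm)
      # re-draw baselines for planted probes so base + delta stays inside
      lo <- ifelse(d > 0, 0.03, 0.03 - pmin(d, 0))
      hi <- ifelse(d > 0, 0.97 - d, 0.97)
      base[dm_idx] <- runif(params$n_dm, lo, hi)
      delta[dm_idx] <- d
    }

    probe_ids <- sprintf("cg%08d", seq_len(p))
    probe_type <- ifelse(runif(p) < params$probe_type_fraction_II, "II", "I")

    samples <- if (paired) {
      tibble(sample = c(paste0(gl[1], "_", seq_len(n_a)),
                        paste0(gl[2], "_", seq_len(n_b))),
             group = rep(gl, c(n_a, n_b)),
             pair_id = rep(seq_len(n_a), 2))
    } else {
      tibble(sample = c(paste0(gl[1], "_", seq_len(n_a)),
                        paste0(gl[2], "_", seq_len(n_b))),
             group = rep(gl, c(n_a, n_b)),
             pair_id = NA_integer_)
    }
    ns <- nrow(samples)
    in_a <- samples$group == gl[1]

    beta_true <- matrix(base, p, ns) +
      outer(delta, as.numeric(in_a))
    beta_obs <- beta_true + matrix(rnorm(p * ns, 0, params$noise_sd), p, ns)
    beta_obs <- pmin(pmax(beta_obs, 1e-4), 1 - 1e-4)
    if (params$type2_attenuation > 0) {
      ii <- probe_type == "II"
      beta_obs[ii, ] <- 0.5 +
        (1 - params$type2_attenuation) * (beta_obs[ii, ] - 0.5)
    }

    total <- matrix(rgamma(p * ns, shape = 50,
                           rate = 50 / params$intensity_scale), p, ns)
    M <- total * beta_obs
    U <- total * (1 - beta_obs)
    detection_p <- matrix(runif(p * ns, 0, 5e-4), p, ns)
    if (params$detection_fail_rate > 0) {
      fail <- runif(p * ns) < params$detection_fail_rate
      detection_p[fail] <- runif(sum(fail), 0.011, 0.5)
    }
    dimnames(M) <- dimnames(U) <- dimnames(detection_p) <-
      list(probe_ids, samples$sample)

    structure(list(
      M = M, U = U, detection_p = detection_p, samples = samples,
      probes = tibble(probe_id = probe_ids, probe_type = probe_type),
      truth = tibble(probe_id = probe_ids[dm_idx],
                     delta_beta = delta[dm_idx],
                     base_beta = base[dm_idx]),
      params = params), class = "meth_sim")
  })
}
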