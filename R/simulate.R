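#' Simulation parameters
#'
#' Parameters of the generative model behind all synthetic assays. Genes
#' carry a methylation level m in \[0, 1\] (a point mass at 0 for the
#' unmethylated fraction, Beta-distributed otherwise). IP libraries enrich
#' methylated transcripts with gain `ip_gain`; reader (RIP) libraries enrich
#' bound transcripts with gain `reader_gain`. A fraction `hypo_fraction` of
#' methylated genes is hypomethylated in the patient condition by the
#' multiplier `hypo_effect`. Decay follows first-order kinetics with rate
#' K = `decay_base` + `decay_coupling` * m for reader-bound transcripts
#' (reader-mediated decay), so hypomethylation slows decay; steady-state
#' abundance under constant synthesis is C0 * K_control / K_condition, which
#' is how stabilization propagates into upregulation.
#'
#' Count noise is negative binomial with one shared dispersion, generated
#' as a gamma latent (shape 1/dispersion, mean 1) times a Poisson draw. The
#' latent is shared between the IP (or RIP) and input libraries of the same
#' replicate, and across timepoints within a decay replicate: fractions of
#' one RNA sample, and one cell line followed over a time course, share
#' their biological abundance fluctuation. Marginal counts are exactly
#' NB(mu, dispersion).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_spikes Number of spike-in species (default 92).
#' @param replicates_per_condition Biological replicates (default 3).
#' @param depth_mean Expected library size in reads (default 2e6).
#' @param depth_cv Coefficient of variation of library size (default 0.1).
#' @param dispersion Shared negative-binomial dispersion (default 0.05).
#' @param unmethylated_fraction Point mass of genes with m = 0 (default 0.4).
#' @param meth_shape1,meth_shape2 Beta shape parameters for methylated
#'   genes' m (default 2, 2).
#' @param ip_gain IP enrichment slope alpha: IP abundance scales with
#'   1 + alpha * m (default 8).
#' @param hypo_fraction Fraction of methylated genes hypomethylated in the
#'   patient condition (default 0.3).
#' @param hypo_effect Multiplier on m for hypomethylated genes, in (0, 1\]
#'   (default 0.4).
#' @param decay_base Baseline decay rate K0 in 1/h (default 0.12).
#' @param decay_coupling Decay rate added per unit methylation for
#'   reader-bound genes, 1/h (default 0.15).
#' @param reader_gain RIP enrichment slope for reader targets (default 6).
#' @param target_fraction Fraction of methylated genes bound by the reader
#'   (default 0.8).
#' @param timepoints_h Decay sampling times in hours (default `c(0, 3, 6)`).
#' @param c0_meanlog,c0_sdlog Log-normal parameters of the baseline
#'   abundance C0 in attomole (defaults log(5), 1).
#' @param seed Integer seed; every generator is deterministic given the
#'   parameter set.
#' @return A list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_genes = 2000,
                              n_spikes = 92,
                              replicates_per_condition = 3,
                              depth_mean = 2e6,
                              depth_cv = 0.1,
                              dispersion = 0.05,
                              unmethylated_fraction = 0.4,
                              meth_shape1 = 2,
                              meth_shape2 = 2,
                              ip_gain = 8,
                              hypo_fraction = 0.3,
                              hypo_effect = 0.4,
                              decay_base = 0.12,
                              decay_coupling = 0.15,
                              reader_gain = 6,
                              target_fraction = 0.8,
                              timepoints_h = c(0, 3, 6),
                              c0_meanlog = log(5),
                              c0_sdlog = 1,
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, n_spikes >= 3, replicates_per_condition >= 1,
    depth_mean > 0, depth_cv >= 0, dispersion >= 0,
    unmethylated_fraction >= 0, unmethylated_fraction <= 1,
    ip_gain > 0, hypo_fraction >= 0, hypo_fraction <= 1,
    hypo_effect > 0, hypo_effect <= 1,
    decay_base > 0, decay_coupling > 0, reader_gain > 0,
    target_fraction >= 0, target_fraction <= 1,
    timepoints_h[1] == 0, length(timepoints_h) >= 2
  )
  structure(as.list(environment()), class = "simulation_params")
}

#' Spike-in reference amounts
#'
#' Deterministic reference table for the simulated spike-in mix: amounts
#' log-spaced over three decades (0.05 to 50 attomole), emulating the broad
#' dynamic range of a commercial spike-in pool while keeping the mix a few
#' percent of the library.
#'
#' @param p A [simulation_params()] object (only `n_spikes` is used).
#' @return Data frame with `spike_id` and `amount_attomole`.
#' @export
spikein_reference <- function(p) {
  n <- p$n_spikes
  data.frame(
    spike_id = sprintf("SPIKE-%03d", seq_len(n)),
    amount_attomole = 10^seq(log10(0.05), log10(50), length.out = n),
    stringsAsFactors = FALSE
  )
}

# gamma latent with mean 1 and variance phi (NB mixing distribution)
.latent_gamma <- function(n, phi) {
  if (phi <= 0) rep(1, n) else stats::rgamma(n, shape = 1 / phi, rate = 1 / phi)
}

# one library-size draw around depth_mean with the configured CV
.draw_depth <- function(p) {
  if (p$depth_cv <= 0) return(p$depth_mean)
  s2 <- log(1 + p$depth_cv^2)
  stats::rlnorm(1, meanlog = log(p$depth_mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate the ground-truth transcriptome
#'
#' Draws per-gene methylation levels, the hypomethylated set, reader-target
#' labels, condition-wise decay rates and baseline abundances. The hypo set
#' has exactly `round(hypo_fraction * n_methylated)` members, sampled from
#' the methylated genes; `K_patient < K_control` exactly for hypomethylated
#' reader targets and `K_patient == K_control` otherwise.
#'
#' @param p A [simulation_params()] object.
#' @return Data frame of class `"ground_truth"`, one row per gene, with
#'   columns `gene_id`, `m_control`, `m_patient`, `is_hypo`,
#'   `is_reader_target`, `k_control`, `k_patient`, `baseline_attomole`
#'   (control steady state C0) and `baseline_attomole_patient` (patient
#'   steady state C0 * k_control / k_patient).
#' @export
simulate_transcriptome <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  set.seed(p$seed)
  n <- p$n_genes
  methylated <- stats::runif(n) >= p$unmethylated_fraction
  m_control <- stats::rbeta(n, p$meth_shape1, p$meth_shape2)
  m_control[!methylated] <- 0
  is_reader_target <- methylated & (stats::runif(n) < p$target_fraction)
  n_hypo <- round(p$hypo_fraction * sum(methylated))
  is_hypo <- rep(FALSE, n)
  if (p$hypo_effect < 1 && n_hypo > 0) {
    is_hypo[sample(which(methylated), n_hypo)] <- TRUE
  }
  m_patient <- ifelse(is_hypo, p$hypo_effect * m_control, m_control)
  k_control <- p$decay_base + p$decay_coupling * m_control * is_reader_target
  k_patient <- p$decay_base + p$decay_coupling * m_patient * is_reader_target
  c0 <- stats::rlnorm(n, meanlog = p$c0_meanlog, sdlog = p$c0_sdlog)
  structure(data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    m_control = m_control,
    m_patient = m_patient,
    is_hypo = is_hypo,
    is_reader_target = is_reader_target,
    k_control = k_control,
    k_patient = k_patient,
    baseline_attomole = c0,
    baseline_attomole_patient = c0 * k_control / k_patient,
    stringsAsFactors = FALSE
  ), class = c("ground_truth", "data.frame"))
}

# condition-wise steady-state baseline abundance
.baseline <- function(gt, condition) {
  if (condition == "control") gt$baseline_attomole else gt$baseline_attomole_patient
}

#' Simulate MeRIP-seq counts (IP and input, both conditions)
#'
#' Input library means are proportional to each condition's baseline
#' abundance; IP means are proportional to baseline * (1 + ip_gain * m),
#' renormalized to the IP library's own depth, so enrichment must be read
#' off relative to input after depth normalization, as with real libraries.
#' The IP and input library of a replicate share their gamma latent
#' (matched fractions of one RNA sample).
#'
#' @param gt Output of [simulate_transcriptome()].
#' @param p The [simulation_params()].
#' @return A [count_matrix()] with samples
#'   condition x assay (IP, input) x replicate.
#' @export
simulate_merip_counts <- function(gt, p) {
  set.seed(p$seed + 101L)
  n <- nrow(gt)
  cols <- list()
  meta <- list()
  for (cond in c("control", "patient")) {
    base <- .baseline(gt, cond)
    m <- if (cond == "control") gt$m_control else gt$m_patient
    w_input <- base
    w_ip <- base * (1 + p$ip_gain * m)
    for (r in seq_len(p$replicates_per_condition)) {
      latent <- .latent_gamma(n, p$dispersion)
      for (assay in c("input", "IP")) {
        w <- if (assay == "IP") w_ip else w_input
        depth <- .draw_depth(p)
        counts <- stats::rpois(n, depth * (w / sum(w)) * latent)
        sid <- sprintf("%s_%s_r%d", cond, assay, r)
        cols[[sid]] <- counts
        meta[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                  assay = assay, timepoint_h = NA_real_,
                                  replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- gt$gene_id
  count_matrix(mat, do.call(rbind, meta), feature_kind = "gene")
}

#' Simulate a decay time course with constant spike-ins
#'
#' True gene abundance is `C0_condition * exp(-K_condition * t)`, starting
#' from each condition's steady state; spike-in amounts are constant across
#' all samples (the same proportion of the mix is added to every sample).
#' Library depth is drawn per sample and counts are proportional to each
#' feature's share of the sample's total RNA mass, so absolute abundance is
#' only recoverable through the spike-in calibration. The gamma latent of a
#' gene is shared across the timepoints of one replicate (one line followed
#' through the time course).
#'
#' With `noiseless = TRUE`, expected counts at fixed depth are emitted
#' (exactly proportional to C(t) within each sample); these are continuous.
#'
#' @param gt Output of [simulate_transcriptome()].
#' @param p The [simulation_params()].
#' @param noiseless Emit expected counts instead of NB draws.
#' @return A [count_matrix()] of genes plus spike-ins across
#'   condition x timepoint x replicate samples (`assay = "input"`).
#' @export
simulate_decay_timecourse <- function(gt, p, noiseless = FALSE) {
  set.seed(p$seed + 202L)
  ref <- spikein_reference(p)
  n <- nrow(gt)
  ns <- nrow(ref)
  cols <- list()
  meta <- list()
  for (cond in c("control", "patient")) {
    base <- .baseline(gt, cond)
    k <- if (cond == "control") gt$k_control else gt$k_patient
    for (r in seq_len(p$replicates_per_condition)) {
      latent <- if (noiseless) rep(1, n) else .latent_gamma(n, p$dispersion)
      for (t in p$timepoints_h) {
        abund <- base * exp(-k * t)
        total <- sum(abund) + sum(ref$amount_attomole)
        if (noiseless) {
          gene_counts <- p$depth_mean * abund / total
          spike_counts <- p$depth_mean * ref$amount_attomole / total
        } else {
          depth <- .draw_depth(p)
          spike_latent <- .latent_gamma(ns, p$dispersion)
          gene_counts <- stats::rpois(n, depth * (abund / total) * latent)
          spike_counts <- stats::rpois(ns, depth * (ref$amount_attomole / total) * spike_latent)
        }
        sid <- sprintf("%s_t%g_r%d", cond, t, r)
        cols[[sid]] <- c(gene_counts, spike_counts)
        meta[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                  assay = "input", timepoint_h = t,
                                  replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- c(gt$gene_id, ref$spike_id)
  count_matrix(mat, do.call(rbind, meta),
               feature_kind = c(rep("gene", n), rep("spikein", ns)),
               allow_fractional = noiseless)
}

#' Simulate reader RIP-seq counts (RIP and input)
#'
#' RIP library means are proportional to baseline * (1 + reader_gain * m)
#' for reader targets and to baseline alone otherwise, renormalized to the
#' RIP library depth. RIP and input share their replicate latent. Sampled
#' in the control background.
#'
#' @param gt Output of [simulate_transcriptome()].
#' @param p The [simulation_params()].
#' @return A [count_matrix()] with RIP and input samples.
#' @export
simulate_rip_counts <- function(gt, p) {
  set.seed(p$seed + 303L)
  n <- nrow(gt)
  base <- gt$baseline_attomole
  w_rip <- base * (1 + p$reader_gain * gt$m_control * gt$is_reader_target)
  w_input <- base
  cols <- list()
  meta <- list()
  for (r in seq_len(p$replicates_per_condition)) {
    latent <- .latent_gamma(n, p$dispersion)
    for (assay in c("input", "RIP")) {
      w <- if (assay == "RIP") w_rip else w_input
      depth <- .draw_depth(p)
      counts <- stats::rpois(n, depth * (w / sum(w)) * latent)
      sid <- sprintf("rip_%s_r%d", assay, r)
      cols[[sid]] <- counts
      meta[[sid]] <- data.frame(sample_id = sid, condition = "control",
                                assay = assay, timepoint_h = NA_real_,
                                replicate = r, stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- gt$gene_id
  count_matrix(mat, do.call(rbind, meta), feature_kind = "gene")
}

#' Simulate a proteomic abundance matrix with missing values
#'
#' Log-normal protein abundances across control and patient samples; a
#' designated protein subset is down-shifted in the patient group, and
#' entries go missing independently at `missing_rate`.
#'
#' @param p The [simulation_params()] (seed and nothing else).
#' @param n_proteins Number of proteins (default 500).
#' @param missing_rate Bernoulli missingness probability in \[0, 1)
#'   (default 0.05).
#' @param n_control,n_patient Samples per group (defaults 8, 8).
#' @param downshift_fraction Fraction of proteins reduced in the patient
#'   group (default 0.1).
#' @param downshift_log2 Size of the reduction on the log2 scale
#'   (default 1).
#' @param sample_sd Within-protein log2 noise sd (default 0.5).
#' @return List with `abundance` (protein x sample matrix, linear scale,
#'   `NA` for missing), `groups` (character vector per sample) and
#'   `is_downshifted` (logical per protein).
#' @export
simulate_proteomics <- function(p, n_proteins = 500, missing_rate = 0.05,
                                n_control = 8, n_patient = 8,
                                downshift_fraction = 0.1,
                                downshift_log2 = 1,
                                sample_sd = 0.5) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  set.seed(p$seed + 404L)
  n_samp <- n_control + n_patient
  groups <- rep(c("control", "patient"), c(n_control, n_patient))
  base <- stats::rnorm(n_proteins, mean = 20, sd = 2)
  down <- rep(FALSE, n_proteins)
  n_down <- round(downshift_fraction * n_proteins)
  if (n_down > 0) down[sample(n_proteins, n_down)] <- TRUE
  lg <- matrix(stats::rnorm(n_proteins * n_samp, sd = sample_sd),
               nrow = n_proteins) + base
  lg[down, groups == "patient"] <- lg[down, groups == "patient"] - downshift_log2
  mat <- 2^lg
  if (missing_rate > 0) {
    mat[stats::runif(length(mat)) < missing_rate] <- NA
  }
  rownames(mat) <- sprintf("prot_%04d", seq_len(n_proteins))
  colnames(mat) <- sprintf("%s_s%02d", groups, stats::ave(seq_len(n_samp),
                                                          groups, FUN = seq_along))
  list(abundance = mat, groups = groups, is_downshifted = down)
}
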