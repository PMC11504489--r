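#' Titration experimental design
#'
#' Defaults reproduce the NMR titration layout the analysis targets: nine
#' samples — one protein-free reference with 2 mM ligand, and eight
#' samples at 0.01 mM protein with ligand at 0.25, 0.5, 0.8, 1.0, 1.5,
#' 2.5, 4.0 and 6.0 mM — with CPMG relaxation delays 0.004 to 2.048 s.
#'
#' @param protein_total protein concentration, mM.
#' @param ligand_totals ligand concentration series, mM.
#' @param reference_total ligand concentration of the protein-free
#'   reference sample, mM.
#' @param delays CPMG relaxation delays, s.
#' @param anomer_fraction_alpha fraction of ligand in the alpha form.
#'   The experiment does not report anomeric ratios; the glucose-like
#'   default alpha:beta ~ 40:60 is an assumption of the simulator.
#' @param noise_sigma noise level; interpreted per `noise_type`.
#' @param noise_type `"relative"`: `noise_sigma` is a fraction of the
#'   dynamic range of the noiseless rates (default 0.02);
#'   `"absolute"`: `noise_sigma` is an SD in s-1.
#' @param replicates number of replicate datasets the design describes.
#' @param seed master seed; replicate r draws from a deterministic child
#'   stream so replicate sets are extensible without reshuffling.
#' @return An object of class `titration_design`.
#' @export
titration_design <- function(protein_total = 0.01,
                             ligand_totals = c(0.25, 0.5, 0.8, 1.0,
                                               1.5, 2.5, 4.0, 6.0),
                             reference_total = 2.0,
                             delays = c(0.004, 0.016, 0.064, 0.128,
                                        0.256, 0.512, 1.024, 2.048),
                             anomer_fraction_alpha = 0.4,
                             noise_sigma = 0.02,
                             noise_type = c("relative", "absolute"),
                             replicates = 1L,
                             seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(protein_total >= 0, all(ligand_totals > 0),
            reference_total > 0, all(delays > 0), all(diff(delays) > 0),
            anomer_fraction_alpha > 0, anomer_fraction_alpha <= 1,
            noise_sigma >= 0, replicates >= 1)
  structure(list(protein_total = protein_total,
                 ligand_totals = ligand_totals,
                 reference_total = reference_total,
                 delays = delays,
                 anomer_fraction_alpha = anomer_fraction_alpha,
                 noise_sigma = noise_sigma, noise_type = noise_type,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "titration_design")
}

#' Competition experimental design
#'
#' Defaults reproduce the competitive titration layout: 0.01 mM protein,
#' the fluorinated probe fixed at 2 mM, and the unlabelled competitor at
#' 0.25, 0.5, 1, 1.5, 2.5, 4, 6, 8 and 10 mM.
#'
#' @param protein_total protein concentration, mM.
#' @param probe_total fixed probe concentration, mM.
#' @param competitor_totals competitor concentration series, mM.
#' @param competitor_kd effective competitor dissociation constant, mM
#'   (`Inf` for a non-binder).
#' @inheritParams titration_design
#' @return An object of class `competition_design`.
#' @export
competition_design <- function(protein_total = 0.01,
                               probe_total = 2.0,
                               competitor_totals = c(0.25, 0.5, 1, 1.5,
                                                     2.5, 4, 6, 8, 10),
                               competitor_kd = 1.0,
                               anomer_fraction_alpha = 0.4,
                               noise_sigma = 0.02,
                               noise_type = c("relative", "absolute"),
                               replicates = 1L,
                               seed = 1L) {
  noise_type <- match.arg(noise_type)
  stopifnot(protein_total >= 0, probe_total > 0,
            all(competitor_totals >= 0), competitor_kd > 0,
            anomer_fraction_alpha > 0, anomer_fraction_alpha <= 1,
            noise_sigma >= 0, replicates >= 1)
  structure(list(protein_total = protein_total,
                 probe_total = probe_total,
                 competitor_totals = competitor_totals,
                 competitor_kd = competitor_kd,
                 anomer_fraction_alpha = anomer_fraction_alpha,
                 noise_sigma = noise_sigma, noise_type = noise_type,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "competition_design")
}

# Deterministic per-replicate child seed of a master seed (32-bit safe).
child_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(replicate)) %%
               .Machine$integer.max)
}

noise_sd <- function(design, rates) {
  if (design$noise_type == "absolute") return(design$noise_sigma)
  design$noise_sigma * (max(rates) - min(rates))
}

#' Simulate a relaxation titration
#'
#' Computes noiseless per-anomer R2 across the design with
#' [predict_titration()], then adds additive Gaussian noise to the rates
#' (including the protein-free reference rates). Bit-reproducible per
#' `(seed, replicate)`. With `return_decays = TRUE` the raw CPMG decay
#' curves are also emitted, with multiplicative Gaussian noise on the
#' intensities at the design's delay schedule.
#'
#' @param design a [titration_design()].
#' @param truth a [binding_parameters()] object used as ground truth.
#' @param replicate replicate index (selects the child noise stream).
#' @param return_decays also generate intensity decay curves?
#' @param i0 reference intensity for simulated decays.
#' @return A [titration_dataset()]; with `return_decays = TRUE` it has an
#'   extra element `decays` (list of [decay_curve()]).
#' @examples
#' simulate_titration(titration_design(noise_sigma = 0),
#'                    binding_parameters(0.87, 0.76, 1310))
#' @export
simulate_titration <- function(design, truth, replicate = 1L,
                               return_decays = FALSE, i0 = 100) {
  stopifnot(inherits(design, "titration_design"),
            inherits(truth, "binding_parameters"))
  pred <- predict_titration(truth, design$protein_total,
                            design$ligand_totals,
                            design$anomer_fraction_alpha)
  rfree <- c(alpha = truth$r_free_alpha, beta = truth$r_free_beta)
  sd_abs <- noise_sd(design, c(pred$r2, rfree))

  set.seed(child_seed(design$seed, replicate))
  rec <- data.frame(
    ligand_total = pred$ligand_total,
    anomer = pred$anomer,
    r2_obs = pred$r2 + stats::rnorm(nrow(pred), 0, sd_abs),
    r2_err = rep(if (sd_abs > 0) sd_abs else NA_real_, nrow(pred)),
    stringsAsFactors = FALSE
  )
  ref <- rfree + stats::rnorm(2L, 0, sd_abs)

  ds <- titration_dataset(design$protein_total, rec, ref,
                          design$anomer_fraction_alpha)
  ds$reference_total <- design$reference_total
  ds$replicate <- as.integer(replicate)

  if (return_decays) {
    rows <- rbind(
      data.frame(sample = paste0("L", pred$ligand_total),
                 anomer = pred$anomer, r2 = rec$r2_obs),
      data.frame(sample = "reference", anomer = c("alpha", "beta"),
                 r2 = ref)
    )
    rel <- if (design$noise_type == "absolute" && max(rows$r2) > 0)
      design$noise_sigma / max(rows$r2) else design$noise_sigma
    ds$decays <- lapply(seq_len(nrow(rows)), function(i) {
      ideal <- i0 * exp(-rows$r2[i] * design$delays)
      decay_curve(design$delays,
                  ideal * (1 + stats::rnorm(length(ideal), 0, rel)),
                  anomer = rows$anomer[i], sample_id = rows$sample[i])
    })
  }
  ds
}

#' Simulate a competitive titration
#'
#' Probe R2 at fixed probe concentration across the competitor series,
#' with additive Gaussian noise; analogous to [simulate_titration()].
#' A competitor with `kd = Inf` yields probe rates identical (before
#' noise) across all competitor points.
#'
#' @param design a [competition_design()].
#' @param probe_truth [binding_parameters()] of the probe.
#' @param replicate replicate index.
#' @return A [competition_dataset()].
#' @export
simulate_competition <- function(design, probe_truth, replicate = 1L) {
  stopifnot(inherits(design, "competition_design"),
            inherits(probe_truth, "binding_parameters"))
  cc <- design$competitor_totals
  pred <- do.call(rbind, lapply(cc, function(c1) {
    comp <- if (c1 > 0)
      species_spec("competitor", c1, design$competitor_kd) else NULL
    p <- predict_titration(probe_truth, design$protein_total,
                           design$probe_total,
                           design$anomer_fraction_alpha,
                           competitor = comp)
    data.frame(competitor_total = c1, anomer = p$anomer, r2 = p$r2)
  }))
  rfree <- c(probe_truth$r_free_alpha, probe_truth$r_free_beta)
  sd_abs <- noise_sd(design, c(pred$r2, rfree))

  set.seed(child_seed(design$seed, replicate))
  rec <- data.frame(
    competitor_total = pred$competitor_total,
    anomer = pred$anomer,
    r2_obs = pred$r2 + stats::rnorm(nrow(pred), 0, sd_abs),
    stringsAsFactors = FALSE
  )
  cd <- competition_dataset(design$protein_total, design$probe_total,
                            rec, design$anomer_fraction_alpha)
  cd$replicate <- as.integer(replicate)
  cd
}

#' Simulate a viability plate
#'
#' Mean response follows a monotone-decreasing four-parameter logistic in
#' percent-of-control units (control wells at 100%), with additive
#' Gaussian replicate noise. The default concentration grid spans the
#' 0.5-20 mM range used for the parent compound in the viability assays.
#'
#' @param ic50 concentration at 50% of control, mM.
#' @param hill Hill slope (> 0).
#' @param concentrations tested concentrations, mM.
#' @param replicates wells per condition.
#' @param noise_sigma SD of the replicate noise, percent-of-control
#'   points.
#' @param seed RNG seed.
#' @param treatment treatment label for the compound wells.
#' @param upper,lower 4PL asymptotes, % of control.
#' @return A [plate_table()] (signals in percent-of-control units, so
#'   [percent_of_control()] recovers the dose-response directly).
#' @examples
#' simulate_viability_plate(ic50 = 3, seed = 11)
#' @export
simulate_viability_plate <- function(ic50, hill = 1.5,
                                     concentrations = c(0.5, 1, 2.5, 5,
                                                        10, 15, 20),
                                     replicates = 3L,
                                     noise_sigma = 5,
                                     seed = 1L,
                                     treatment = "compound",
                                     upper = 100, lower = 0) {
  stopifnot(ic50 > 0, hill > 0, all(concentrations > 0),
            replicates >= 1, noise_sigma >= 0)
  x_mid <- ic50 * ((upper - lower) / (50 - lower) - 1)^(-1 / hill)
  mu <- lower + (upper - lower) / (1 + (concentrations / x_mid)^hill)

  set.seed(as.integer(seed))
  n <- length(concentrations)
  rec <- rbind(
    data.frame(treatment = "control", concentration = 0,
               replicate = seq_len(replicates),
               signal = 100 + stats::rnorm(replicates, 0, noise_sigma)),
    data.frame(treatment = treatment,
               concentration = rep(concentrations, each = replicates),
               replicate = rep(seq_len(replicates), n),
               signal = rep(mu, each = replicates) +
                 stats::rnorm(n * replicates, 0, noise_sigma))
  )
  plate_table(rec, control = "control")
}
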