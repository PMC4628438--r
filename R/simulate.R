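#' Simulation configuration for synthetic AFLP intensity data
#'
#' Defaults mirror the study design the package was built around: 93
#' isolates from 78 clonal lineages typed at 30 retained loci on 3
#' plates with dual technical replicates, sampled across 3 areas x 3
#' crops with no habitat association. Present bands fluoresce around 800
#' RFU and background around 10 RFU (log-normal with log-sd 0.4), far
#' from the 100/50 calling thresholds; dropout and mutation rates are
#' small plausibility choices for a well-run AFLP assay.
#'
#' @param n_isolates Number of isolates.
#' @param n_loci Number of scored fragment-size loci.
#' @param n_lineages Number of clonal lineages (each gets at least one
#'   isolate; must not exceed `n_isolates`).
#' @param p_present Probability a lineage carries a band at a locus.
#' @param mutation_rate Per-locus flip probability, isolate vs lineage.
#' @param mu_present,mu_absent Median intensity (RFU) of present bands /
#'   background signal.
#' @param sigma_present,sigma_absent Log-scale spread of the two
#'   intensity distributions.
#' @param dropout_prob Probability that a truly present band yields a
#'   background-level signal, independently per technical replicate.
#' @param plate_effect_sd Log-scale spread of the multiplicative plate
#'   factor shared by all bands on a plate.
#' @param n_plates Number of 96-well plates; the first isolate serves as
#'   the plate control and is re-run on every plate.
#' @param areas,crops Category labels for the sampling design.
#' @param association_strength In \[0, 1\]: weight of the lineage's home
#'   habitat when assigning area/crop (0 = uniform, no structure; 1 =
#'   every lineage confined to one habitat).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_isolates = 93L, n_loci = 30L, n_lineages = 78L,
                              p_present = 0.5, mutation_rate = 0.01,
                              mu_present = 800, sigma_present = 0.4,
                              mu_absent = 10, sigma_absent = 0.4,
                              dropout_prob = 0.02, plate_effect_sd = 0.1,
                              n_plates = 3L,
                              areas = c("Faarevejle", "Skibby", "Taastrup"),
                              crops = c("oilseed_rape", "winter_wheat", "grass_pasture"),
                              association_strength = 0, seed = 1L) {
  cfg <- list(n_isolates = as.integer(n_isolates), n_loci = as.integer(n_loci),
              n_lineages = as.integer(n_lineages), p_present = p_present,
              mutation_rate = mutation_rate, mu_present = mu_present,
              sigma_present = sigma_present, mu_absent = mu_absent,
              sigma_absent = sigma_absent, dropout_prob = dropout_prob,
              plate_effect_sd = plate_effect_sd, n_plates = as.integer(n_plates),
              areas = as.character(areas), crops = as.character(crops),
              association_strength = association_strength, seed = as.integer(seed))
  for (f in c("n_isolates", "n_loci", "n_lineages", "n_plates")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop("invalid config: ", f, " must be a positive integer")
  }
  for (f in c("p_present", "mutation_rate", "dropout_prob", "association_strength")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("invalid config: ", f, " must lie in [0, 1]")
  }
  for (f in c("sigma_present", "sigma_absent", "plate_effect_sd")) {
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  }
  if (cfg$mu_present <= 0 || cfg$mu_absent <= 0) {
    stop("invalid config: mu_present and mu_absent must be positive")
  }
  if (cfg$n_lineages > cfg$n_isolates) stop("invalid config: n_lineages exceeds n_isolates")
  if (length(cfg$areas) < 1L || length(cfg$crops) < 1L) {
    stop("invalid config: areas and crops must be non-empty")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a fragment-intensity dataset with known clonal ground truth
#'
#' Generates lineage band profiles (Bernoulli `p_present` per locus),
#' assigns every lineage at least one isolate, flips each isolate's loci
#' independently at `mutation_rate`, and emits two technical replicates
#' per isolate: present bands draw log-normal intensities around
#' `mu_present` (times a shared multiplicative plate factor), absent
#' bands draw background around `mu_absent`, and with `dropout_prob` a
#' truly present band collapses to a background draw independently per
#' replicate — so the calling rule's replicate-disagreement branch is
#' exercised. The first isolate is the plate control: plate-suffixed
#' copies (e.g. `ISO001.p2`) are run on every other plate, preserving the
#' uniqueness of (isolate, replicate, locus) keys. Areas and crops mix a
#' uniform draw (weight `1 - association_strength`) with the lineage's
#' home habitat (weight `association_strength`).
#'
#' @param config A [simulation_config()].
#' @return A list with `intensities` (intensity table data.frame,
#'   `(n_isolates + n_plates - 1) * 2 * n_loci` rows) and `truth`, a list
#'   holding `lineage_of` (named integer vector over real isolates),
#'   `true_profiles` (lineage x locus matrix), `isolate_profiles`
#'   (post-mutation truth per isolate), `metadata` (incl. control
#'   aliases), `control_id` and `control_aliases`.
#' @export
simulate_aflp <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_isolates; L <- config$n_loci; K <- config$n_lineages
  iso_ids <- sprintf("ISO%03d", seq_len(n))
  locus_ids <- sprintf("L%03d", seq_len(L))
  lineage_profiles <- matrix(stats::rbinom(K * L, 1L, config$p_present), K, L,
                             dimnames = list(sprintf("LIN%03d", seq_len(K)), locus_ids))
  lineage_of <- sample(c(seq_len(K),
                         if (n > K) sample.int(K, n - K, replace = TRUE)))
  names(lineage_of) <- iso_ids
  flips <- matrix(stats::rbinom(n * L, 1L, config$mutation_rate), n, L)
  iso_profiles <- (lineage_profiles[lineage_of, , drop = FALSE] + flips) %% 2L
  dimnames(iso_profiles) <- list(iso_ids, locus_ids)
  # habitat assignment
  home_area <- sample(config$areas, K, replace = TRUE)
  home_crop <- sample(config$crops, K, replace = TRUE)
  use_home <- stats::runif(n) < config$association_strength
  area <- ifelse(use_home, home_area[lineage_of], sample(config$areas, n, replace = TRUE))
  crop <- ifelse(use_home, home_crop[lineage_of], sample(config$crops, n, replace = TRUE))
  # plates: round-robin over isolates; control copies on every other plate
  plate_of <- rep(seq_len(config$n_plates), length.out = n)
  plate_factor <- exp(stats::rnorm(config$n_plates, 0, config$plate_effect_sd))
  control_id <- iso_ids[1L]
  extra_plates <- setdiff(seq_len(config$n_plates), plate_of[1L])
  control_aliases <- if (length(extra_plates) > 0L) {
    sprintf("%s.p%d", control_id, extra_plates)
  } else character(0)
  all_ids <- c(iso_ids, control_aliases)
  all_truth <- rbind(iso_profiles,
                     iso_profiles[rep(1L, length(control_aliases)), , drop = FALSE])
  rownames(all_truth) <- all_ids
  all_plate <- c(plate_of, extra_plates)
  m <- length(all_ids)
  draw_intensity <- function(present, fac) {
    mu <- ifelse(present, log(config$mu_present), log(config$mu_absent))
    sg <- ifelse(present, config$sigma_present, config$sigma_absent)
    exp(stats::rnorm(length(mu), mu, sg)) * fac
  }
  recs <- vector("list", 2L * m)
  for (rep_i in 1:2) {
    present <- all_truth == 1L
    dropped <- matrix(stats::runif(m * L) < config$dropout_prob, m, L) & present
    effective <- present & !dropped
    fac <- plate_factor[all_plate][row(effective)]
    intensity <- draw_intensity(as.vector(effective), as.vector(fac))
    recs[[rep_i]] <- data.frame(
      isolate_id = rep(all_ids, times = L),
      replicate = rep_i,
      plate_id = sprintf("P%d", all_plate[rep(seq_len(m), times = L)]),
      locus_id = rep(locus_ids, each = m),
      intensity = round(intensity, 2),
      stringsAsFactors = FALSE
    )
  }
  intensities <- do.call(rbind, recs)
  intensities <- intensities[order(intensities$isolate_id, intensities$locus_id,
                                   intensities$replicate), ]
  rownames(intensities) <- NULL
  metadata <- data.frame(
    isolate_id = all_ids,
    area = c(area, rep(area[1L], length(control_aliases))),
    crop = c(crop, rep(crop[1L], length(control_aliases))),
    origin = "study",
    stringsAsFactors = FALSE
  )
  validate_intensity_table(intensities)
  list(intensities = intensities,
       truth = list(lineage_of = lineage_of, true_profiles = lineage_profiles,
                    isolate_profiles = iso_profiles, metadata = metadata,
                    control_id = control_id, control_aliases = control_aliases))
}

#' Simulate a multinomial contingency table
#'
#' Draws `n` counts from a joint distribution over `length(row_probs) x
#' length(col_probs)` cells. With `association = 0` the joint is the
#' product of the margins (the null of homogeneity); with `association >
#' 0` it is mixed with a matched-diagonal component concentrating mass on
#' cells `(i, i)`, producing a simple departure from independence.
#'
#' @param row_probs,col_probs Probability vectors summing to 1 (within
#'   1e-9).
#' @param n Total count.
#' @param association Mixing weight in \[0, 1\] of the diagonal
#'   component.
#' @param seed Integer RNG seed.
#' @return Integer matrix of counts summing to `n`.
#' @export
simulate_contingency <- function(row_probs, col_probs, n, association = 0,
                                 seed = 1L) {
  if (abs(sum(row_probs) - 1) > 1e-9 || abs(sum(col_probs) - 1) > 1e-9) {
    stop("probability vectors must sum to 1")
  }
  if (any(row_probs < 0) || any(col_probs < 0)) stop("probabilities must be non-negative")
  if (association < 0 || association > 1) stop("association must lie in [0, 1]")
  if (n < 1) stop("n must be a positive integer")
  r <- length(row_probs); k <- length(col_probs)
  joint <- outer(row_probs, col_probs)
  if (association > 0) {
    diag_part <- matrix(0, r, k)
    kk <- min(r, k)
    w <- row_probs[seq_len(kk)]
    if (sum(w) == 0) w <- rep(1, kk)
    diag_part[cbind(seq_len(kk), seq_len(kk))] <- w / sum(w)
    joint <- (1 - association) * joint + association * diag_part
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- stats::rmultinom(1L, n, as.vector(joint))
  matrix(as.integer(counts), r, k,
         dimnames = list(names(row_probs), names(col_probs)))
}
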