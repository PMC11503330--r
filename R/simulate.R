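#' Specification of a synthetic tiled-array study
#'
#' Describes a synthetic serology experiment: a random proteome tiled into
#' overlapping 16-mers (a fraction of proteins also carried as a
#' citrullinated series), log-normal background fluorescence, a small number
#' of planted disease-specific antigens spanning consecutive tiles, and the
#' group sizes of the contrast. Defaults emulate the study conditions this
#' package targets: 8 disease vs 16 control subjects, a roughly 50,000-
#' peptide library, background calibrated so that about 1% of cells exceed
#' the whole-array mu + 3 sigma threshold, antigens spanning 3-5 consecutive
#' tiles with 8-16x signal in 75% of disease subjects.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length Length range (min, max) in residues.
#' @param n_exp,n_con Subjects per contrast arm (>= 2 each).
#' @param background_meanlog,background_sdlog Log-normal background
#'   parameters on the raw fluorescence scale.
#' @param n_antigens Number of planted disease-specific antigens.
#' @param tiles_per_antigen Range of consecutive tiles per antigen.
#' @param effect_range Range of the per-antigen intensity multiplier
#'   (applied to responder disease subjects only; must exceed 1).
#' @param responder_fraction Fraction of disease subjects elevated per
#'   antigen, in (0, 1].
#' @param citrulline_planting Probability a planted antigen is placed in a
#'   citrullinated series (when one is available).
#' @param modified_fraction Fraction of proteins also represented as a
#'   citrullinated tile series.
#' @param r_freq,k_freq Arginine / lysine frequencies of the random
#'   proteome; the remaining mass is spread uniformly over the other 18
#'   residues.
#' @param tile_length,step Tiling geometry.
#' @return An object of class \code{"signal_spec"}.
#' @export
signal_spec <- function(n_proteins = 330L, protein_length = c(280L, 320L),
                        n_exp = 8L, n_con = 16L,
                        background_meanlog = 6.2, background_sdlog = 0.3,
                        n_antigens = 24L, tiles_per_antigen = c(3L, 5L),
                        effect_range = c(8, 16), responder_fraction = 0.75,
                        citrulline_planting = 0.5, modified_fraction = 0.05,
                        r_freq = 0.05, k_freq = 0.06,
                        tile_length = 16L, step = 2L) {
  stopifnot(n_proteins >= 1L, length(protein_length) == 2L,
            protein_length[1] >= 16L, protein_length[2] >= protein_length[1],
            n_exp >= 2L, n_con >= 2L, background_sdlog > 0,
            n_antigens >= 0L, length(tiles_per_antigen) == 2L,
            tiles_per_antigen[1] >= 1L,
            all(effect_range >= 1), effect_range[2] >= effect_range[1],
            responder_fraction > 0, responder_fraction <= 1,
            citrulline_planting >= 0, citrulline_planting <= 1,
            modified_fraction >= 0, modified_fraction <= 1,
            r_freq >= 0, k_freq >= 0, r_freq + k_freq < 1)
  structure(as.list(environment()), class = "signal_spec")
}

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Generate a random synthetic proteome
#'
#' Sequences are i.i.d. draws over the 20-residue alphabet with configurable
#' arginine and lysine frequencies; reproducible per seed (R's default
#' Mersenne-Twister stream).
#'
#' @param spec A \code{\link{signal_spec}}.
#' @param seed Integer seed.
#' @return Data frame with \code{protein_id}, \code{sequence}.
#' @export
generate_proteome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(seed)
  aa <- aa_alphabet()
  prob <- rep((1 - spec$r_freq - spec$k_freq) / 18, 20)
  prob[aa == "R"] <- spec$r_freq
  prob[aa == "K"] <- spec$k_freq
  lens <- sample(spec$protein_length[1]:spec$protein_length[2],
                 spec$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  data.frame(
    protein_id = sprintf("SP%04d", seq_len(spec$n_proteins)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

## tile a proteome into the library described by spec: native series for
## every protein, a citrullinated series for the sampled fraction
tile_proteome <- function(proteome, spec) {
  native <- do.call(rbind, Map(tile_protein, proteome$protein_id,
                               proteome$sequence,
                               MoreArgs = list(tile_length = spec$tile_length,
                                               step = spec$step)))
  n_mod <- round(spec$modified_fraction * nrow(proteome))
  if (n_mod > 0L) {
    mod_prot <- sample(proteome$protein_id, n_mod)
    cit <- apply_modification(native[native$protein_id %in% mod_prot, ],
                              "citrullinated")
    native <- rbind(native, cit)
  }
  peptide_library(native, step = spec$step)
}

#' Generate a synthetic array experiment with planted antigens
#'
#' Background intensities are i.i.d. log-normal. Each planted antigen picks
#' a run of consecutive tiles in one (protein, series); for responder
#' subjects of the disease arm the intensities of those tiles are multiplied
#' by the antigen's effect multiplier, so overlapping tiles share elevated
#' signal exactly as a real linear epitope would. Ground truth (planted
#' peptides, responders, ELISA-validity flags) is recorded.
#'
#' @param proteome From \code{\link{generate_proteome}}.
#' @param spec A \code{\link{signal_spec}}.
#' @param seed Integer seed.
#' @return List with \code{library} (\code{\link{peptide_library}}),
#'   \code{experiment} (\code{\link{array_experiment}}), \code{design}
#'   (\code{\link{group_design}}) and \code{truth} (class
#'   \code{"ground_truth"}: \code{antigens} data frame, \code{planted_ids},
#'   \code{responders} per antigen, \code{elisa_valid} named flags).
#' @export
generate_experiment <- function(proteome, spec, seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(seed + 1L)
  library <- tile_proteome(proteome, spec)
  r <- library$records
  n_pep <- nrow(r)

  subjects <- c(sprintf("exp%02d", seq_len(spec$n_exp)),
                sprintf("con%02d", seq_len(spec$n_con)))
  groups <- stats::setNames(rep(c("disease", "control"),
                                c(spec$n_exp, spec$n_con)), subjects)
  design <- group_design(groups, experimental = "disease",
                         control = "control")

  intensity <- matrix(
    stats::rlnorm(n_pep * length(subjects),
                  meanlog = spec$background_meanlog,
                  sdlog = spec$background_sdlog),
    nrow = n_pep, ncol = length(subjects),
    dimnames = list(r$peptide_id, subjects))

  series_key <- paste(r$protein_id, r$modification, sep = "\r")
  series <- split(seq_len(n_pep), series_key)   # row indices, start-ordered
  exp_subjects <- subjects[seq_len(spec$n_exp)]

  antigens <- data.frame(antigen_id = character(), peptide_id = character(),
                         stringsAsFactors = FALSE)
  responders <- list()
  multipliers <- numeric()
  if (spec$n_antigens > 0L) {
    is_cit <- grepl("citrullinated", names(series), fixed = TRUE)
    want_cit <- stats::runif(spec$n_antigens) < spec$citrulline_planting
    if (!any(is_cit)) want_cit[] <- FALSE
    min_len <- spec$tiles_per_antigen[2]
    eligible_cit <- which(is_cit & lengths(series) >= min_len)
    eligible_nat <- which(!is_cit & lengths(series) >= min_len)
    n_cit <- min(sum(want_cit), length(eligible_cit))
    n_nat <- min(spec$n_antigens - n_cit, length(eligible_nat))
    chosen <- c(sample_int(eligible_cit, n_cit),
                sample_int(eligible_nat, n_nat))
    if (length(chosen) < spec$n_antigens)
      stop("generate_experiment: not enough series to plant ",
           spec$n_antigens, " antigens")
    n_resp <- max(1L, round(spec$responder_fraction * spec$n_exp))
    for (i in seq_along(chosen)) {
      rows <- series[[chosen[i]]]
      len <- sample_int(spec$tiles_per_antigen[1]:spec$tiles_per_antigen[2], 1L)
      at <- sample_int(seq_len(length(rows) - len + 1L), 1L)
      planted_rows <- rows[at:(at + len - 1L)]
      resp <- sample_int(seq_len(spec$n_exp), n_resp)
      mult <- stats::runif(1, spec$effect_range[1], spec$effect_range[2])
      intensity[planted_rows, exp_subjects[resp]] <-
        intensity[planted_rows, exp_subjects[resp]] * mult
      aid <- sprintf("antigen%02d", i)
      antigens <- rbind(antigens,
                        data.frame(antigen_id = aid,
                                   peptide_id = r$peptide_id[planted_rows],
                                   stringsAsFactors = FALSE))
      responders[[aid]] <- exp_subjects[resp]
      multipliers[aid] <- mult
    }
  }
  planted_ids <- unique(antigens$peptide_id)
  truth <- structure(list(
    antigens = antigens,
    planted_ids = planted_ids,
    responders = responders,
    multipliers = multipliers,
    elisa_valid = stats::setNames(rep(TRUE, length(planted_ids)),
                                  planted_ids)),
    class = "ground_truth")

  list(library = library,
       experiment = array_experiment(intensity, library),
       design = design,
       truth = truth)
}

## sample() without its scalar-x surprise
sample_int <- function(x, n) x[sample.int(length(x), n)]

#' Simulate ELISA absorbances coupled to array signal
#'
#' For each requested peptide: absorbance = baseline + slope * z + noise,
#' truncated at 0 OD, where z is the peptide's array intensity standardized
#' across subjects. The slope applies only to peptides flagged ELISA-valid
#' in the ground truth — an ELISA against a peptide whose array signal was
#' artifactual reproduces nothing, so invalid and unplanted peptides get
#' noise around the baseline. Setting \code{coupling_slope = 0} decouples
#' everything (the null configuration).
#'
#' @param experiment An \code{\link{array_experiment}}.
#' @param truth The \code{"ground_truth"} from
#'   \code{\link{generate_experiment}}.
#' @param peptides Peptide ids to assay.
#' @param coupling_slope OD change per standard deviation of array signal
#'   for valid peptides, default 0.5.
#' @param noise_sd Gaussian noise on the OD scale, default 0.05.
#' @param baseline Baseline OD, default 0.5.
#' @param seed Integer seed.
#' @return Long data frame: \code{peptide_id}, \code{subject_id},
#'   \code{absorbance}.
#' @export
simulate_elisa <- function(experiment, truth, peptides,
                           coupling_slope = 0.6, noise_sd = 0.05,
                           baseline = 0.2, seed = 1L) {
  stopifnot(inherits(experiment, "array_experiment"),
            inherits(truth, "ground_truth"))
  if (noise_sd < 0) stop("simulate_elisa: negative noise_sd")
  peptides <- as.character(peptides)
  missing <- setdiff(peptides, rownames(experiment$intensity))
  if (length(missing) > 0L)
    stop("simulate_elisa: unknown peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  set.seed(seed + 2L)
  subjects <- experiment$subjects
  valid_ids <- names(truth$elisa_valid)[truth$elisa_valid]
  rows <- lapply(peptides, function(id) {
    x <- experiment$intensity[id, ]
    s <- stats::sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    slope <- if (id %in% valid_ids) coupling_slope else 0
    absorb <- pmax(0, baseline + slope * z +
                     stats::rnorm(length(x), 0, noise_sd))
    data.frame(peptide_id = id, subject_id = subjects,
               absorbance = unname(absorb), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic study
#'
#' Generates the proteome, the planted array experiment, and coupled ELISA
#' measurements for a labeled training panel (half planted, half unplanted
#' by default, mirroring a panel picked from array hits and controls).
#'
#' @param spec A \code{\link{signal_spec}}.
#' @param seed Integer seed driving every stage.
#' @param n_labeled Size of the ELISA-assayed training panel, default 70.
#' @param labeled_planted_fraction Fraction of the panel drawn from planted
#'   peptides, default 0.5.
#' @param coupling_slope,noise_sd,baseline Passed to
#'   \code{\link{simulate_elisa}}.
#' @return List: \code{library}, \code{experiment}, \code{design},
#'   \code{truth}, \code{elisa} (long data frame), \code{training_ids}.
#' @export
simulate_study <- function(spec = signal_spec(), seed = 1L, n_labeled = 70L,
                           labeled_planted_fraction = 0.5,
                           coupling_slope = 0.6, noise_sd = 0.05,
                           baseline = 0.2) {
  proteome <- generate_proteome(spec, seed)
  gen <- generate_experiment(proteome, spec, seed)
  set.seed(seed + 3L)
  planted <- gen$truth$planted_ids
  n_planted <- min(round(labeled_planted_fraction * n_labeled),
                   length(planted))
  others <- setdiff(gen$library$records$peptide_id, planted)
  training_ids <- c(sample_int(planted, n_planted),
                    sample_int(others, n_labeled - n_planted))
  elisa <- simulate_elisa(gen$experiment, gen$truth, training_ids,
                          coupling_slope = coupling_slope,
                          noise_sd = noise_sd, baseline = baseline,
                          seed = seed)
  c(gen, list(elisa = elisa, training_ids = training_ids))
}
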