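# Seeded synthetic chemical libraries with planted substructure-activity
# associations. The generator assembles guaranteed-valid SMILES from a
# scaffold/substituent grammar (template substitution, never graph surgery),
# plants activity-associated motifs, and draws activity labels from a
# logistic model in the planted motif effects.

# Built-in motif vocabulary. `fragment` is the substituent-form SMILES used
# for assembly; `chemotype` names the built-in chemotype that detects it.
.MOTIF_VOCAB <- data.frame(
  motif = c("triazine", "phenol", "aromatic_amine", "biphenyl_diamine",
            "phosphorodithioate", "aryl_halide"),
  # ring-closure digits 8/9 so fragments can sit inside an open scaffold ring
  fragment = c("c8nc(N)nc(N)n8",
               "c8ccc(O)cc8",
               "c8ccc(N)cc8",
               "c8cc(N)ccc8-c9ccc(N)cc9",
               "SP(=S)(OC)OC",
               "c8ccc(Cl)cc8"),
  chemotype = c("ring_hetero_triazine", "bond_COH_phenol",
                "bond_CN_amine_aromatic", "ring_aromatic_biphenyl",
                "bond_PS_phosphorothioate", "bond_CX_halide_aromatic"),
  stringsAsFactors = FALSE
)

# Background scaffolds written as templates. Every scaffold carries two
# dedicated motif slots ({M1}, {M2}) and one independent random-substituent
# slot ({S1}); unused slots are deleted together with their parentheses.
# Dedicated slots keep motif planting independent of the background
# decoration, so a planted motif never displaces other features (which
# would otherwise read as spurious depletion in enrichment scans).
.SCAFFOLDS <- c(
  "c1c({M2})cc({S1})cc1{M1}",
  "c1c({M2})nc({S1})cc1{M1}",
  "C1CC({M2})CC({S1})C1{M1}",
  "CC({M2})CC({S1})CC{M1}",
  "CCOC(=O)C({M2})C({S1}){M1}"
)

.SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "F", "C(=O)OC", "C#N",
                   "N(C)C", "CO", "OCC", "C(C)C")

#' Built-in motif vocabulary of the synthetic library generator
#'
#' Six substructure families recurrently associated with increased estradiol
#' or progesterone synthesis in structure-activity profiling of the H295R
#' screening library: amino-substituted 1,3,5-triazines, phenols, aromatic
#' primary amines, biphenyl diamines (benzidine-like), phosphorodithioate
#' esters and aryl halides.
#'
#' @return A data frame with columns `motif` (identifier), `fragment`
#'   (substituent-form SMILES planted by [generate_library()]) and
#'   `chemotype` (the built-in chemotype name that detects the motif, see
#'   [builtin_chemotypes()]).
#' @export
motif_vocabulary <- function() .MOTIF_VOCAB

#' Configuration for a synthetic chemical library
#'
#' @param n_chemicals Number of chemicals to generate (positive integer).
#' @param active_rate Baseline probability of activity for a chemical
#'   carrying no effect motif; fraction in (0, 1). Default 0.10, the
#'   approximate active prevalence of the H295R concentration-response set.
#' @param motif_effects Named numeric vector mapping motif identifiers (see
#'   [motif_vocabulary()]) to odds ratios >= 1. Motifs not named have odds
#'   ratio 1 (planted as inert background structure).
#' @param label_noise Probability in [0, 0.5) that a drawn label is flipped.
#' @param seed Integer seed; the whole library is a deterministic function
#'   of the configuration.
#' @param motif_prevalence Per-motif planting probability (each motif is
#'   planted independently). Default 0.08, giving motif-bearing minorities
#'   comparable to chemotype prevalences seen in screening libraries.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chemicals, active_rate = 0.10,
                             motif_effects = numeric(0), label_noise = 0,
                             seed = 1L, motif_prevalence = 0.08) {
  if (!is.numeric(n_chemicals) || length(n_chemicals) != 1L ||
      is.na(n_chemicals) || n_chemicals < 1 || n_chemicals != floor(n_chemicals))
    stop("invalid configuration: 'n_chemicals' must be a positive integer")
  if (!is.numeric(active_rate) || length(active_rate) != 1L ||
      is.na(active_rate) || active_rate <= 0 || active_rate >= 1)
    stop("invalid configuration: 'active_rate' must lie in (0, 1)")
  if (length(motif_effects)) {
    if (is.null(names(motif_effects)) || any(!nzchar(names(motif_effects))))
      stop("invalid configuration: 'motif_effects' must be a named vector")
    unknown <- setdiff(names(motif_effects), .MOTIF_VOCAB$motif)
    if (length(unknown))
      stop("invalid configuration: 'motif_effects' names unknown motif(s): ",
           paste(unknown, collapse = ", "))
    if (any(!is.finite(motif_effects)) || any(motif_effects < 1))
      stop("invalid configuration: 'motif_effects' odds ratios must be >= 1")
  }
  if (!is.numeric(label_noise) || length(label_noise) != 1L ||
      is.na(label_noise) || label_noise < 0 || label_noise >= 0.5)
    stop("invalid configuration: 'label_noise' must lie in [0, 0.5)")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed))
    stop("invalid configuration: 'seed' must be an integer")
  if (!is.numeric(motif_prevalence) || length(motif_prevalence) != 1L ||
      is.na(motif_prevalence) || motif_prevalence <= 0 || motif_prevalence >= 1)
    stop("invalid configuration: 'motif_prevalence' must lie in (0, 1)")
  structure(list(n_chemicals = as.integer(n_chemicals),
                 active_rate = active_rate,
                 motif_effects = motif_effects,
                 label_noise = label_noise,
                 seed = as.integer(seed),
                 motif_prevalence = motif_prevalence),
            class = "synthetic_config")
}

#' Draw an activity label from planted motifs
#'
#' Activity is Bernoulli with log-odds equal to the logit of the baseline
#' active rate plus the sum of log odds ratios of the planted effect motifs;
#' the drawn label is then flipped with probability `label_noise`.
#'
#' @param true_motifs Character vector of motif identifiers planted in the
#'   chemical (may be empty).
#' @param config A [synthetic_config()].
#' @param draw Uniform deviate in [0, 1) deciding the activity Bernoulli.
#' @param noise_draw Optional second uniform deviate in [0, 1) deciding the
#'   label flip; required when `label_noise > 0`.
#' @return Integer label: 1 (active) or 0 (inactive).
#' @export
assign_activity <- function(true_motifs, config, draw, noise_draw = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(draw) || length(draw) != 1L || is.na(draw) ||
      draw < 0 || draw >= 1)
    stop("'draw' must be a uniform deviate in [0, 1)")
  eff <- config$motif_effects[intersect(true_motifs, names(config$motif_effects))]
  p <- stats::plogis(stats::qlogis(config$active_rate) + sum(log(eff)))
  label <- as.integer(draw < p)
  if (config$label_noise > 0) {
    if (is.null(noise_draw))
      stop("'noise_draw' is required when label_noise > 0")
    if (noise_draw < config$label_noise) label <- 1L - label
  }
  label
}

#' Generate a synthetic chemical library
#'
#' Assembles `n_chemicals` valid SMILES from a scaffold/substituent grammar,
#' plants motifs from [motif_vocabulary()] independently with the configured
#' prevalence (at most two per chemical, slots permitting), and draws a
#' binary activity label per chemical from the logistic motif-effect model
#' of [assign_activity()]. The output is a deterministic function of the
#' configuration, including its seed.
#'
#' @param config A [synthetic_config()].
#' @param endpoint Endpoint name attached to the labels table. Default
#'   `"E2up"`.
#' @return An object of class `synthetic_library`: a list with `records`
#'   (data frame: id, casrn, name, smiles), `labels` (id, endpoint, active),
#'   `truth` (id, motifs as comma-joined string, p_active, active) and the
#'   `config`. Every SMILES parses and is salt-free and single-fragment.
#' @export
generate_library <- function(config, endpoint = "E2up") {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_chemicals
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  vocab <- .MOTIF_VOCAB
  planted <- matrix(stats::runif(n * nrow(vocab)) < config$motif_prevalence,
                    nrow = n)
  scaffold_idx <- sample.int(length(.SCAFFOLDS), n, replace = TRUE)
  act_draw <- stats::runif(n)
  noise_draw <- stats::runif(n)

  smiles <- character(n)
  motif_str <- character(n)
  p_active <- numeric(n)
  active <- integer(n)
  sub_draw <- stats::runif(n)
  sub_pick <- sample.int(length(.SUBSTITUENTS), n, replace = TRUE)
  fill_slot <- function(smi, token, frag) {
    if (is.na(frag)) {
      smi <- sub(paste0("(", token, ")"), "", smi, fixed = TRUE)
      sub(token, "", smi, fixed = TRUE)   # bare (unparenthesised) slot
    } else {
      sub(token, frag, smi, fixed = TRUE)
    }
  }
  for (i in seq_len(n)) {
    tmpl <- .SCAFFOLDS[scaffold_idx[i]]
    motifs_i <- vocab$motif[planted[i, ]]
    frags <- vocab$fragment[planted[i, ]]
    if (length(frags) > 2L) {               # cap at the two motif slots
      motifs_i <- motifs_i[1:2]
      frags <- frags[1:2]
    }
    frags <- c(frags, rep(NA_character_, 2L - length(frags)))
    # the decoration slot is filled independently of motif planting
    s1 <- if (sub_draw[i] < 0.6) .SUBSTITUENTS[sub_pick[i]] else NA_character_
    smi <- fill_slot(tmpl, "{M1}", frags[1])
    smi <- fill_slot(smi, "{M2}", frags[2])
    smi <- fill_slot(smi, "{S1}", s1)
    smiles[i] <- smi
    motif_str[i] <- paste(motifs_i, collapse = ",")
    eff <- config$motif_effects[intersect(motifs_i, names(config$motif_effects))]
    p_active[i] <- stats::plogis(stats::qlogis(config$active_rate) +
                                   sum(log(eff)))
    lab <- as.integer(act_draw[i] < p_active[i])
    if (config$label_noise > 0 && noise_draw[i] < config$label_noise)
      lab <- 1L - lab
    active[i] <- lab
  }

  ids <- sprintf("CHEM%05d", seq_len(n))
  records <- data.frame(
    id = ids,
    casrn = sprintf("SYN-%05d-0", seq_len(n)),
    name = sprintf("synthetic-%05d", seq_len(n)),
    smiles = smiles,
    stringsAsFactors = FALSE
  )
  labels <- data.frame(id = ids, endpoint = endpoint, active = active,
                       stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, motifs = motif_str, p_active = p_active,
                      active = active, stringsAsFactors = FALSE)
  structure(list(records = records, labels = labels, truth = truth,
                 config = config),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat("Synthetic chemical library:", nrow(x$records), "chemicals,",
      sum(x$labels$active), "active (",
      sprintf("%.1f%%", 100 * mean(x$labels$active)), ")\n")
  eff <- x$config$motif_effects
  if (length(eff))
    cat("Effect motifs:",
        paste(sprintf("%s (OR=%g)", names(eff), eff), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic library to disk
#'
#' Writes `library.csv` (id, casrn, name, smiles), `labels.csv`
#' (id, endpoint, active) and `truth.json` into `dir`.
#'
#' @param lib A [generate_library()] result.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "synthetic_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("library.csv", "labels.csv", "truth.json"))
  utils::write.csv(lib$records, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(lib$labels, paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lib$truth, paths[3], dataframe = "rows", digits = NA)
  invisible(paths)
}
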