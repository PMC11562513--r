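## Synthetic trial cohort generator: reference proteome, per-patient somatic
## variants, HLA alleles, vaccine designs (via the toy binding ensemble),
## ground-truth immunogenicity labels, assay readouts (ELISpot, ICS, CDR3b
## clonotypes) and follow-up, all reproducible from a single seed.
##
## Defaults emulate the cohort structure of an 18-patient adjuvant TNBC
## DNA-vaccine trial: ~21.5 expressed protein-altering mutations per patient
## (median), 97% missense, 4-20 vaccinated epitopes per patient, ~23% of
## vaccinated epitopes truly immunogenic, and a 2/18 recurrence rate with a
## higher-hazard unvaccinated comparison arm (~49% 3-year RFS).

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of vaccinated patients.
#' @param n_proteins reference proteome size.
#' @param protein_length_range protein length range (residues, min >= 30).
#' @param mutations_per_patient_median Poisson mean for expressed
#'   protein-altering mutations per patient.
#' @param missense_fraction fraction of variants that are missense (the
#'   remainder are frameshift/indel).
#' @param immunogenic_fraction fraction of vaccinated epitopes that are
#'   truly immunogenic (ground truth).
#' @param elispot_noise negative-binomial size (dispersion) of ELISpot well
#'   counts; larger = less overdispersed.
#' @param ics_noise sd (percentage points) of ICS percent-positive readouts.
#' @param n_clonotypes clonotypes per simulated repertoire.
#' @param clonotype_depth sequencing depth (cells) per repertoire.
#' @param expansion_factor frequency fold applied to truth clonotypes
#'   post-vaccination.
#' @param recurrence_rate per-patient recurrence probability in the
#'   vaccinated arm.
#' @param n_controls size of the unvaccinated comparison arm.
#' @param control_rfs_36 target 36-month recurrence-free survival of the
#'   comparison arm (sets its exponential hazard).
#' @param n_wells ELISpot replicate wells per condition.
#' @param alleles HLA class I allele pool (patients get two each of A/B/C).
#' @param seed master seed; identical config + seed gives byte-identical
#'   output.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 18L, n_proteins = 100L,
                          protein_length_range = c(60L, 300L),
                          mutations_per_patient_median = 21.5,
                          missense_fraction = 0.97,
                          immunogenic_fraction = 0.23,
                          elispot_noise = 20, ics_noise = 0.15,
                          n_clonotypes = 500L, clonotype_depth = 10000L,
                          expansion_factor = 20,
                          recurrence_rate = 2 / 18, n_controls = 60L,
                          control_rfs_36 = 0.49, n_wells = 3L,
                          alleles = toy_alleles(), seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              mutations_per_patient_median = mutations_per_patient_median,
              missense_fraction = missense_fraction,
              immunogenic_fraction = immunogenic_fraction,
              elispot_noise = elispot_noise, ics_noise = ics_noise,
              n_clonotypes = as.integer(n_clonotypes),
              clonotype_depth = as.integer(clonotype_depth),
              expansion_factor = expansion_factor,
              recurrence_rate = recurrence_rate,
              n_controls = as.integer(n_controls),
              control_rfs_36 = control_rfs_36, n_wells = as.integer(n_wells),
              alleles = alleles, seed = as.integer(seed))
  props <- c("missense_fraction", "immunogenic_fraction", "recurrence_rate",
             "control_rfs_36")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop_input(p, " must be a proportion in [0, 1]")
  counts <- c("n_patients", "n_proteins", "n_clonotypes", "clonotype_depth",
              "n_controls", "n_wells")
  for (p in counts)
    if (is.na(cfg[[p]]) || cfg[[p]] < 1L)
      stop_input(p, " must be a positive count")
  if (length(cfg$protein_length_range) != 2L ||
      any(is.na(cfg$protein_length_range)) ||
      cfg$protein_length_range[1L] < 30L ||
      diff(cfg$protein_length_range) < 0L)
    stop_input("protein_length_range must be an increasing pair with ",
               "minimum length >= 30 residues")
  if (cfg$mutations_per_patient_median <= 0 || cfg$elispot_noise <= 0 ||
      cfg$ics_noise <= 0 || cfg$expansion_factor <= 0)
    stop_input("rates, dispersions and folds must be positive")
  structure(cfg, class = "cohort_config")
}

stage_seed <- function(config, stage) string_seed(stage, config$seed)

patient_ids <- function(config) sprintf("P%02d", seq_len(config$n_patients))

#' Generate the synthetic reference proteome and expression table
#'
#' @param config a [cohort_config()].
#' @param seed optional override seed (defaults to a stage seed derived
#'   from the config seed).
#' @return list with `proteins` (named character vector of canonical-residue
#'   sequences) and `expression` (data frame `protein_id`, `tpm`).
#' @export
generate_proteome <- function(config, seed = NULL) {
  set.seed(seed %||% stage_seed(config, "proteome"))
  r <- config$protein_length_range
  lens <- r[1L] + sample.int(r[2L] - r[1L] + 1L, config$n_proteins,
                             replace = TRUE) - 1L
  prots <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  names(prots) <- sprintf("PROT%04d", seq_len(config$n_proteins))
  expr <- data.frame(protein_id = names(prots),
                     tpm = round(rlnorm_pos(config$n_proteins), 3),
                     stringsAsFactors = FALSE)
  list(proteins = prots, expression = expr)
}

## log-normal TPM with a spike of unexpressed transcripts (~10%)
rlnorm_pos <- function(n) {
  tpm <- exp(rnorm(n, mean = 2, sd = 1.2))
  tpm[runif(n) < 0.1] <- 0
  tpm
}

#' Assign HLA class I alleles to each patient
#'
#' Two alleles per locus (A, B, C) sampled from the configured pool.
#'
#' @param config a [cohort_config()].
#' @param seed optional override seed.
#' @return named list of character vectors (6 alleles per patient).
#' @export
assign_hla <- function(config, seed = NULL) {
  set.seed(seed %||% stage_seed(config, "hla"))
  loci <- split(config$alleles, substr(config$alleles, 5L, 5L))
  setNames(lapply(patient_ids(config), function(p)
    unlist(lapply(loci, sample, size = min(2L, length(loci[[1L]])),
                  replace = TRUE), use.names = FALSE)),
    patient_ids(config))
}

#' Simulate per-patient somatic variant tables
#'
#' Per patient, a Poisson draw (mean = configured median) of expressed
#' protein-altering variants; each variant carries its type (missense or
#' frameshift), a valid 1-based position with the true reference residue,
#' VAF, expression (TPM and mutant-allele RNA reads) and a driver flag.
#'
#' @param proteome from [generate_proteome()].
#' @param config a [cohort_config()].
#' @param seed optional override seed.
#' @return data frame, one row per variant.
#' @export
simulate_variants <- function(proteome, config, seed = NULL) {
  if (!length(proteome$proteins)) stop_input("proteome is empty")
  set.seed(seed %||% stage_seed(config, "variants"))
  tpm_of <- setNames(proteome$expression$tpm, proteome$expression$protein_id)
  out <- list()
  for (pat in patient_ids(config)) {
    n <- max(1L, rpois(1L, config$mutations_per_patient_median))
    pid <- sample(names(proteome$proteins), n, replace = TRUE)
    pos <- vapply(pid, function(g)
      sample.int(nchar(proteome$proteins[[g]]), 1L), integer(1))
    ref <- unname(substring(proteome$proteins[pid], pos, pos))
    miss <- runif(n) < config$missense_fraction
    alt <- character(n)
    alt[miss] <- vapply(ref[miss], function(r)
      sample(setdiff(AA20, r), 1L), character(1))
    alt[!miss] <- vapply(which(!miss), function(i)
      paste(sample(AA20, sample(8:24, 1L), replace = TRUE), collapse = ""),
      character(1))
    vaf <- round(runif(n, 0.02, 0.6), 3)
    tpm <- unname(tpm_of[pid])
    rna_alt <- rpois(n, lambda = pmax(0.2, tpm / 4) * vaf * 2)
    out[[pat]] <- data.frame(
      patient_id = pat, protein_id = pid, position = pos, ref = ref,
      alt = alt, type = ifelse(miss, "missense", "frameshift"),
      vaf = vaf, tpm = tpm, rna_alt_reads = rna_alt,
      driver_flag = runif(n) < 0.15, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Design vaccines for every patient in a synthetic cohort
#'
#' Runs the full prioritization pipeline per patient: windows, minimal
#' epitope enumeration against the patient's alleles, toy-ensemble scoring,
#' candidate annotation, filtering and ranked selection of 4-20 windows.
#' Deterministic given its inputs (no RNG).
#'
#' @param variants variant table from [simulate_variants()].
#' @param proteome from [generate_proteome()].
#' @param hla from [assign_hla()].
#' @param thresholds prioritization thresholds.
#' @param min_select,max_select selection bounds.
#' @return named list per patient: `selection` (with `mt_sequence` joined),
#'   `windows`, `candidates`, `relax_level`, `n_selected`.
#' @export
design_vaccines <- function(variants, proteome, hla,
                            thresholds = default_thresholds(),
                            min_select = 4L, max_select = 20L) {
  designs <- list()
  for (pat in unique(variants$patient_id)) {
    v <- variants[variants$patient_id == pat, , drop = FALSE]
    wins <- build_windows(v, proteome$proteins)
    pairs <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i)
      enumerate_minimal_epitopes(as.list(wins[i, ]),
                                 alleles = hla[[pat]])))
    scored <- score_epitopes(pairs)
    cand <- annotate_candidates(scored, wins, proteome$proteins, thresholds)
    sel <- rank_and_select(cand, min_select = min_select,
                           max_select = max_select, thresholds = thresholds)
    sdf <- sel$selection
    sdf$mt_sequence <- wins$mt_sequence[match(sdf$window_id,
                                              wins$neoantigen_id)]
    designs[[pat]] <- list(selection = sdf, windows = wins,
                           candidates = cand, relax_level = sel$relax_level,
                           n_selected = sel$n_selected)
  }
  designs
}

#' Label ground-truth immunogenic epitopes among vaccinated windows
#'
#' @param designs from [design_vaccines()].
#' @param config a [cohort_config()].
#' @param seed optional override seed.
#' @return data frame (`patient`, `neoantigen`) of truly immunogenic
#'   vaccinated epitopes (possibly zero rows).
#' @export
assign_ground_truth <- function(designs, config, seed = NULL) {
  set.seed(seed %||% stage_seed(config, "truth"))
  rows <- list()
  for (pat in names(designs)) {
    ids <- designs[[pat]]$selection$window_id
    hit <- runif(length(ids)) < config$immunogenic_fraction
    if (any(hit))
      rows[[pat]] <- data.frame(patient = pat, neoantigen = ids[hit],
                                stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(patient = character(0), neoantigen = character(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

random_cdr3b <- function(n) {
  vapply(seq_len(n), function(i)
    paste0("CASS", paste(sample(AA20, sample(5:9, 1L), replace = TRUE),
                         collapse = ""), "F"), character(1))
}

#' Simulate assay readouts for a designed cohort
#'
#' ELISpot wells (negative-binomial counts; no-peptide background means in
#' the 10-120 SFC/10^6 range), ICS percent-positive readouts, and CDR3-beta
#' clonotype tables pre/post vaccination. Truly immunogenic epitopes get a
#' post-vaccination ELISpot effect (log-normal, mean several hundred SFC),
#' ICS readouts satisfying the positivity rule with high probability, and
#' 1-3 clonotypes spiked by the configured expansion factor; all other
#' epitopes share the background distributions pre and post.
#'
#' @param designs from [design_vaccines()].
#' @param truth ground-truth immunogenic epitopes, as from
#'   [assign_ground_truth()]; every row must reference a vaccinated epitope.
#' @param config a [cohort_config()].
#' @param seed optional override seed.
#' @return list with `elispot`, `ics`, `clonotypes` (tidy data frames) and
#'   `expanded_clonotypes` (ground-truth expanded clones).
#' @export
simulate_assays <- function(designs, truth, config, seed = NULL) {
  set.seed(seed %||% stage_seed(config, "assays"))
  key <- paste(truth$patient, truth$neoantigen)
  vac <- unlist(lapply(names(designs), function(p)
    paste(p, designs[[p]]$selection$window_id)))
  if (!all(key %in% vac))
    stop_input("ground-truth epitope(s) not present in any vaccine design")
  nb <- function(n, mu) rnbinom(n, mu = mu, size = config$elispot_noise)
  nw <- config$n_wells
  eli <- list(); ics <- list(); clono <- list(); expanded <- list()
  for (pat in names(designs)) {
    sel <- designs[[pat]]$selection
    if (!nrow(sel)) next
    bg_mu <- runif(2L, 20, 100)  # pre, post plate backgrounds
    eli[[length(eli) + 1L]] <- data.frame(
      patient = pat, neoantigen = NA_character_, stimulus = "none",
      timepoint = rep(c("pre", "post"), each = nw), well = rep(1:nw, 2L),
      count = c(nb(nw, bg_mu[1L]), nb(nw, bg_mu[2L])),
      stringsAsFactors = FALSE)
    cdr3 <- random_cdr3b(config$n_clonotypes)
    w_base <- rgamma(config$n_clonotypes, shape = 0.5)
    for (k in seq_len(nrow(sel))) {
      neo <- sel$window_id[k]
      imm <- paste(pat, neo) %in% key
      effect <- if (imm) exp(rnorm(1L, log(600), 0.8)) else 0
      shares <- if (imm && runif(1) < 0.5) {
        s <- rep(0.1, 3L); s[sample.int(3L, 1L)] <- 0.8; s
      } else { s <- runif(3L, 0.25, 0.4); s / sum(s) }
      stim_mu <- list(
        pool = c(bg_mu[1L], bg_mu[2L] + effect),
        OP1 = c(bg_mu[1L], bg_mu[2L] + shares[1L] * effect),
        OP2 = c(bg_mu[1L], bg_mu[2L] + shares[2L] * effect),
        OP3 = c(bg_mu[1L], bg_mu[2L] + shares[3L] * effect),
        `MT-S` = c(bg_mu[1L], bg_mu[2L] + effect * runif(1, 0.8, 1.2)),
        `WT-S` = c(bg_mu[1L], bg_mu[2L] + effect * runif(1, 0, 0.05)))
      for (st in names(stim_mu)) {
        eli[[length(eli) + 1L]] <- data.frame(
          patient = pat, neoantigen = neo, stimulus = st,
          timepoint = rep(c("pre", "post"), each = nw),
          well = rep(1:nw, 2L),
          count = c(nb(nw, stim_mu[[st]][1L]), nb(nw, stim_mu[[st]][2L])),
          stringsAsFactors = FALSE)
      }
      for (subset in c("CD8", "CD4")) {
        pre <- min(100, max(0, rnorm(1L, 0.2, config$ics_noise)))
        post_mu <- if (!imm) 0.2
        else if (subset == "CD8") 2.5
        else if (runif(1) < 0.5) 1.5 else 0.25
        post <- min(100, max(0, rnorm(1L, post_mu, 2 * config$ics_noise)))
        ics[[length(ics) + 1L]] <- data.frame(
          patient = pat, neoantigen = neo, subset = subset,
          percent_pre = pre, percent_post = post, stringsAsFactors = FALSE)
      }
      pre_counts <- as.integer(rmultinom(1L, config$clonotype_depth, w_base))
      w_post <- w_base
      if (imm) {
        eligible <- which(w_base / sum(w_base) * config$clonotype_depth >= 5)
        picks <- sample(eligible, min(length(eligible), sample(1:3, 1L)))
        w_post[picks] <- w_post[picks] * config$expansion_factor
        if (length(picks))
          expanded[[length(expanded) + 1L]] <- data.frame(
            patient = pat, neoantigen = neo, cdr3b = cdr3[picks],
            stringsAsFactors = FALSE)
      }
      post_counts <- as.integer(rmultinom(1L, config$clonotype_depth,
                                          w_post))
      keep <- pre_counts > 0L | post_counts > 0L
      clono[[length(clono) + 1L]] <- data.frame(
        patient = pat, neoantigen = neo,
        timepoint = rep(c("pre", "post"), each = sum(keep)),
        cdr3b = rep(cdr3[keep], 2L),
        count = c(pre_counts[keep], post_counts[keep]),
        stringsAsFactors = FALSE)
    }
  }
  list(elispot = do.call(rbind, eli), ics = do.call(rbind, ics),
       clonotypes = do.call(rbind, clono),
       expanded_clonotypes = if (length(expanded)) do.call(rbind, expanded)
       else data.frame(patient = character(0), neoantigen = character(0),
                       cdr3b = character(0)))
}

#' Simulate follow-up for the vaccinated arm and a comparison arm
#'
#' Vaccinated patients recur with the configured probability (event times
#' uniform over months 3-30, censoring around 36 months of follow-up); the
#' unvaccinated comparison arm has an exponential hazard calibrated to the
#' configured 36-month recurrence-free survival.
#'
#' @param config a [cohort_config()].
#' @param seed optional override seed.
#' @return data frame with `subject`, `arm`, `time` (months, > 0), `event`.
#' @export
simulate_followup <- function(config, seed = NULL) {
  set.seed(seed %||% stage_seed(config, "followup"))
  n <- config$n_patients
  ev <- runif(n) < config$recurrence_rate
  time <- ifelse(ev, runif(n, 3, 30), runif(n, 30, 42))
  vac <- data.frame(subject = patient_ids(config), arm = "vaccinated",
                    time = round(time, 2), event = ev,
                    stringsAsFactors = FALSE)
  rate <- -log(config$control_rfs_36) / 36
  tt <- rexp(config$n_controls, rate)
  cc <- runif(config$n_controls, 36, 48)
  ctl <- data.frame(subject = sprintf("C%03d", seq_len(config$n_controls)),
                    arm = "control", time = round(pmin(tt, cc), 2),
                    event = tt <= cc, stringsAsFactors = FALSE)
  rbind(vac, ctl)
}

#' Simulate a complete synthetic trial cohort
#'
#' Runs every generator stage (proteome, HLA, variants, vaccine design via
#' the toy binding ensemble, ground-truth labels, assays, follow-up) from
#' the config's master seed. Identical config gives byte-identical output.
#'
#' @param config a [cohort_config()].
#' @return list of class `neovax_cohort` with elements `config`, `proteome`,
#'   `hla`, `variants`, `designs`, `ground_truth` (immunogenic epitopes,
#'   expanded clonotypes, event times), `elispot`, `ics`, `clonotypes`,
#'   `followup`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  proteome <- generate_proteome(config)
  hla <- assign_hla(config)
  variants <- simulate_variants(proteome, config)
  designs <- design_vaccines(variants, proteome, hla)
  truth <- assign_ground_truth(designs, config)
  assays <- simulate_assays(designs, truth, config)
  followup <- simulate_followup(config)
  structure(list(
    config = config, proteome = proteome, hla = hla, variants = variants,
    designs = designs,
    ground_truth = list(
      immunogenic_epitopes = truth,
      expanded_clonotypes = assays$expanded_clonotypes,
      event_times = setNames(followup$time[followup$arm == "vaccinated"],
                             followup$subject[followup$arm == "vaccinated"])),
    elispot = assays$elispot, ics = assays$ics,
    clonotypes = assays$clonotypes, followup = followup),
    class = "neovax_cohort")
}

#' @export
print.neovax_cohort <- function(x, ...) {
  sel <- vapply(x$designs, function(d) d$n_selected, integer(1))
  cat("Synthetic neoantigen vaccine cohort\n")
  cat("  patients:", x$config$n_patients,
      " variants:", nrow(x$variants), "\n")
  cat("  epitopes per vaccine: median", median(sel), "range",
      min(sel), "-", max(sel), "\n")
  cat("  ground-truth immunogenic epitopes:",
      nrow(x$ground_truth$immunogenic_epitopes), "of", sum(sel), "\n")
  invisible(x)
}
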