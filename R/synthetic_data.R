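#' Configuration for the synthetic database generator
#'
#' The generator emulates the summary-statistic output of a moderated
#' differential-expression fit (one logFC and p per comparison and gene)
#' across a small multi-study senescence corpus. It does not simulate
#' reads or counts.
#'
#' Defaults describe the study conditions the recovery analyses assume:
#' four inducers (DDIS, OIS, REP, BYS) with ten studies each and two
#' senescent-vs-proliferating comparisons per study; a gene panel of 20
#' core-signature genes (significant in all four inducers), 30
#' inducer-specific genes and 150 null genes; residual biological noise
#' sd 0.3 on the logFC scale, between-study sd 0.2, three replicates per
#' arm, and a 1% rate of gross logFC outliers of magnitude 6.
#'
#' @param studies_per_inducer Studies simulated per inducer.
#' @param comparisons_per_study Senescent-vs-control comparisons per study.
#' @param intervention_comparisons Per inducer, extra comparisons carrying
#'   each intervention flag (`p53_inhibition`, `RelA_inhibition`).
#' @param replicates_n Replicates per arm behind each comparison (>= 2).
#' @param residual_sd Within-study residual sd of logFC (sigma > 0).
#' @param study_sd Between-study sd of the gene-level study effect (tau).
#' @param outlier_prob Probability a gene-stat row receives a gross error.
#' @param outlier_shift Magnitude of the gross error added to logFC.
#' @param n_core,n_specific,n_null Panel sizes for core-signature,
#'   inducer-specific and null genes.
#' @param seed Integer seed; the generator uses R's default Mersenne
#'   Twister stream and is deterministic given the seed.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(studies_per_inducer = 10,
                             comparisons_per_study = 2,
                             intervention_comparisons = 6,
                             replicates_n = 3,
                             residual_sd = 0.3,
                             study_sd = 0.2,
                             outlier_prob = 0.01,
                             outlier_shift = 6,
                             n_core = 20,
                             n_specific = 30,
                             n_null = 150,
                             seed = 1L) {
  cfg <- list(studies_per_inducer = studies_per_inducer,
              comparisons_per_study = comparisons_per_study,
              intervention_comparisons = intervention_comparisons,
              replicates_n = replicates_n,
              residual_sd = residual_sd, study_sd = study_sd,
              outlier_prob = outlier_prob, outlier_shift = outlier_shift,
              n_core = n_core, n_specific = n_specific, n_null = n_null,
              seed = as.integer(seed))
  if (cfg$studies_per_inducer < 1 || cfg$comparisons_per_study < 1)
    stop("counts must be >= 1")
  if (cfg$replicates_n < 2) stop("replicates_n must be >= 2")
  if (cfg$residual_sd <= 0) stop("residual_sd must be positive")
  if (cfg$study_sd < 0) stop("study_sd must be nonnegative")
  if (cfg$outlier_prob < 0 || cfg$outlier_prob > 1)
    stop("outlier_prob must be in [0, 1]")
  if (cfg$n_core + cfg$n_specific + cfg$n_null < 1)
    stop("empty gene panel")
  structure(cfg, class = "generator_config")
}

#' Planted-effect specification for the generator
#'
#' Mean logFC per (gene, inducer, time bin), with unspecified triples
#' defaulting to 0, plus multiplicative intervention modifiers per
#' (intervention, gene). The default specification built by
#' [default_effect_spec()] plants: core-signature genes at logFC +1 (half)
#' or -1 (half) in every inducer and bin; inducer-specific genes at +/-1
#' only in their own inducer; marker-style profiles for named senescence
#' genes (CDKN1A up from the earliest bin in DDIS but only from day 5 in
#' OIS; CDKN2A higher and earlier in OIS than DDIS; MDM2 DDIS-biased;
#' IL6/CXCL8/IL1B rising from day 5; HES1/HEY1 up then down); and
#' intervention modifiers 0.2 on CDKN1A and MDM2 under p53 inhibition and
#' 0.2 on IL6/CXCL8/IL1B under RelA inhibition.
#'
#' @param effects Data frame with columns `gene`, `inducer`, `time_bin`
#'   (`"*"` matches any bin), `mean_logfc`.
#' @param modifiers Data frame with columns `intervention`, `gene`,
#'   `multiplier`.
#' @return A list of class `"effect_spec"`.
#' @export
effect_spec <- function(effects, modifiers = NULL) {
  stopifnot(all(c("gene", "inducer", "time_bin", "mean_logfc") %in%
                  names(effects)))
  if (is.null(modifiers))
    modifiers <- data.frame(intervention = character(), gene = character(),
                            multiplier = numeric())
  if (any(!is.finite(effects$mean_logfc))) stop("non-finite planted effect")
  structure(list(effects = effects, modifiers = modifiers),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @param config A [generator_config()]; panel sizes set how many core /
#'   inducer-specific / null genes are named.
#' @export
default_effect_spec <- function(config = generator_config()) {
  inducers <- c("DDIS", "OIS", "REP", "BYS")
  core <- sprintf("CORE%03d", seq_len(config$n_core))
  core_sign <- rep(c(1, -1), length.out = config$n_core)
  spec <- expand.grid(gene = core, inducer = inducers,
                      stringsAsFactors = FALSE)
  spec$time_bin <- "*"
  spec$mean_logfc <- core_sign[match(spec$gene, core)]
  specific <- sprintf("SPEC%03d", seq_len(config$n_specific))
  sp_ind <- rep(inducers, length.out = config$n_specific)
  sp <- data.frame(gene = specific, inducer = sp_ind, time_bin = "*",
                   mean_logfc = rep(c(1, -1),
                                    length.out = config$n_specific),
                   stringsAsFactors = FALSE)
  # Marker-style temporal profiles used by the figure-style analyses.
  early_bins <- "D0_4"
  late_bins <- c("D5_7", "D8_11", "D12_14", "D15plus")
  mk <- function(gene, inducer, bins, lfc)
    data.frame(gene = gene, inducer = inducer, time_bin = bins,
               mean_logfc = lfc, stringsAsFactors = FALSE)
  markers <- rbind(
    mk("CDKN1A", "DDIS", c(early_bins, late_bins), 1.2),
    mk("CDKN1A", "OIS", late_bins, 1.0),
    mk("CDKN2A", "OIS", c(early_bins, late_bins), 1.5),
    mk("CDKN2A", "DDIS", late_bins, 0.6),
    mk("MDM2", "DDIS", c(early_bins, late_bins), 1.2),
    mk("MDM2", "OIS", c(early_bins, late_bins), 0.4),
    mk("IL6", c("DDIS", "OIS"), rep(late_bins, each = 2), 1.2),
    mk("CXCL8", c("DDIS", "OIS"), rep(late_bins, each = 2), 1.2),
    mk("IL1B", c("DDIS", "OIS"), rep(late_bins, each = 2), 1.0),
    mk("HES1", c("DDIS", "OIS"), "D0_4", 0.8),
    mk("HES1", c("DDIS", "OIS"), rep(c("D8_11", "D12_14", "D15plus"),
                                     each = 2), -0.6),
    mk("HEY1", c("DDIS", "OIS"), c("D0_4", "D0_4", "D5_7", "D5_7"), 0.8),
    mk("HEY1", c("DDIS", "OIS"), rep(c("D8_11", "D12_14", "D15plus"),
                                     each = 2), -0.6))
  effects <- rbind(spec, sp, markers, make.row.names = FALSE)
  modifiers <- data.frame(
    intervention = c("p53_inhibition", "p53_inhibition",
                     "RelA_inhibition", "RelA_inhibition",
                     "RelA_inhibition"),
    gene = c("CDKN1A", "MDM2", "IL6", "CXCL8", "IL1B"),
    multiplier = 0.2, stringsAsFactors = FALSE)
  effect_spec(effects, modifiers)
}

#' Gene panel implied by a configuration
#'
#' Core, inducer-specific and null genes are synthetic symbols; the eight
#' named marker genes with temporal profiles are always included as a
#' fourth category.
#' @keywords internal
gene_panel <- function(config) {
  list(core = sprintf("CORE%03d", seq_len(config$n_core)),
       specific = sprintf("SPEC%03d", seq_len(config$n_specific)),
       null = sprintf("NULL%03d", seq_len(config$n_null)),
       marker = c("CDKN1A", "CDKN2A", "MDM2", "IL6", "CXCL8", "IL1B",
                  "HES1", "HEY1"))
}

#' Draw one gene-stat row under the coherent t model
#'
#' The observed logFC is `mean + study_effect + residual`, with
#' `study_effect ~ N(0, tau^2)` supplied by the caller (shared across a
#' study) and `residual ~ N(0, 2 sigma^2 / n)` reflecting a two-arm
#' comparison with `n` replicates per arm. The p-value simulates the
#' two-sample t-test the source studies would report: a pooled variance
#' estimate `s^2 ~ sigma^2 chi^2_df / df` is drawn (df = 2n - 2) and the
#' two-sided tail of `t = logFC / (s * sqrt(2 / n))` on df degrees of
#' freedom is returned, so p is exactly uniform for a null gene without
#' study effects and p and logFC share the same noise realisation. With
#' probability `outlier_prob` a gross error of `+/- outlier_shift` is then
#' added to the logFC (after p is computed) and the row is flagged.
#'
#' @param mean Planted mean logFC (vectorised).
#' @param study_effect Study-level offsets, same length as `mean`.
#' @param config A [generator_config()].
#' @return Data frame with `logFC`, `p`, `outlier` columns. Consumes the
#'   current RNG stream.
#' @export
sample_gene_stat <- function(mean, study_effect = 0, config) {
  n <- length(mean)
  study_effect <- rep_len(study_effect, n)
  se <- config$residual_sd * sqrt(2 / config$replicates_n)
  logfc <- mean + study_effect + stats::rnorm(n, 0, se)
  df <- 2 * config$replicates_n - 2
  s <- config$residual_sd * sqrt(stats::rchisq(n, df) / df)
  tstat <- logfc / (s * sqrt(2 / config$replicates_n))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p <- pmax(p, .Machine$double.xmin)  # keep within (0, 1]
  is_out <- stats::runif(n) < config$outlier_prob
  shift <- sample(c(-1, 1), n, replace = TRUE) * config$outlier_shift
  logfc[is_out] <- logfc[is_out] + shift[is_out]
  data.frame(logFC = logfc, p = p, outlier = is_out)
}

planted_mean <- function(gene, inducer, bin, spec) {
  e <- spec$effects
  m <- numeric(length(gene))
  key_any <- paste(e$gene, e$inducer, "*")
  key_bin <- paste(e$gene, e$inducer, e$time_bin)
  i_bin <- match(paste(gene, inducer, bin), key_bin)
  i_any <- match(paste(gene, inducer, "*"), key_any)
  m <- ifelse(!is.na(i_bin), e$mean_logfc[i_bin],
              ifelse(!is.na(i_any), e$mean_logfc[i_any], 0))
  m
}

#' Generate a synthetic comparison database with ground truth
#'
#' Builds a full three-table database ([load_database()] layout) for the
#' four meta-analysed inducers plus a planted-truth table. Each study gets
#' a cell line, day-denominated comparison times spanning the bin scheme
#' (REP studies get PD-denominated times), and per-(study, gene) random
#' effects; additional comparisons carry the `p53_inhibition` and
#' `RelA_inhibition` flags at days 1-11 with planted intervention
#' multipliers applied. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param spec An [effect_spec()]; defaults to [default_effect_spec()].
#' @return A list of class `"senodb"` with the extra element `truth`:
#'   a list with `classes` (per gene x inducer planted class `up` /
#'   `down` / `null`) and `outliers` (per gene-stat row flag, aligned
#'   with `genestats`).
#' @export
generate_database <- function(config = generator_config(),
                              spec = default_effect_spec(config)) {
  set.seed(config$seed)
  panel <- gene_panel(config)
  genes <- unlist(panel, use.names = FALSE)
  if (!length(genes)) stop("empty gene panel")
  inducers <- c("DDIS", "OIS", "REP", "BYS")
  day_pool <- c(1, 2, 3, 4, 6, 7, 9, 10, 13, 16)
  studies <- list(); comparisons <- list()
  cell_pool <- c("IMR90", "WI38", "BJ", "MRC5", "HFF")
  for (ind in inducers) {
    for (s in seq_len(config$studies_per_inducer)) {
      acc <- sprintf("SYN-%s-%02d", ind, s)
      cell <- sample(cell_pool, 1)
      if (ind == "REP") {
        tv <- sample(c(30, 45, 60, 75, 90), config$comparisons_per_study,
                     replace = TRUE)
        tu <- "PD"
      } else {
        tv <- sample(day_pool, config$comparisons_per_study,
                     replace = TRUE)
        tu <- "days"
      }
      studies[[acc]] <- data.frame(
        accession = acc, inducers = ind, control_types = "proliferating",
        cell_lines = cell,
        timepoints = paste(sprintf("%g:%s", tv, tu), collapse = ";"),
        platform = "rnaseq", stringsAsFactors = FALSE)
      comparisons[[acc]] <- data.frame(
        comparison_id = sprintf("%s-c%d", acc,
                                seq_len(config$comparisons_per_study)),
        study_accession = acc, inducer = ind,
        control_type = "proliferating", cell_line = cell,
        time_value = tv, time_unit = tu, intervention = "none",
        platform = "rnaseq", stringsAsFactors = FALSE)
    }
    if (ind != "REP" && config$intervention_comparisons > 0) {
      # one study per intervention comparison: the contrasts assume
      # independent study-level effects across the inhibited group
      for (iv in c("p53_inhibition", "RelA_inhibition")) {
        for (k in seq_len(config$intervention_comparisons)) {
          acc <- sprintf("SYN-%s-%s-%02d", ind,
                         toupper(substr(iv, 1, 3)), k)
          tv <- sample(c(2, 4, 6, 8, 10), 1)
          studies[[acc]] <- data.frame(
            accession = acc, inducers = ind,
            control_types = "proliferating", cell_lines = "IMR90",
            timepoints = sprintf("%g:days", tv),
            platform = "rnaseq", stringsAsFactors = FALSE)
          comparisons[[acc]] <- data.frame(
            comparison_id = sprintf("%s-c1", acc),
            study_accession = acc, inducer = ind,
            control_type = "proliferating", cell_line = "IMR90",
            time_value = tv, time_unit = "days", intervention = iv,
            platform = "rnaseq", stringsAsFactors = FALSE)
        }
      }
    }
  }
  studies <- do.call(rbind, c(studies, make.row.names = FALSE))
  comparisons <- do.call(rbind, c(comparisons, make.row.names = FALSE))
  comparisons <- bin_comparisons(comparisons)

  # study-level random effect per (study, gene)
  ng <- length(genes)
  study_fx <- matrix(stats::rnorm(nrow(studies) * ng, 0, config$study_sd),
                     nrow(studies), ng,
                     dimnames = list(studies$accession, genes))
  gs <- vector("list", nrow(comparisons))
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    mu <- planted_mean(genes, cmp$inducer, cmp$time_bin, spec)
    if (cmp$intervention != "none") {
      mod <- spec$modifiers[spec$modifiers$intervention == cmp$intervention,
                            , drop = FALSE]
      j <- match(genes, mod$gene)
      mu <- ifelse(is.na(j), mu, mu * mod$multiplier[j])
    }
    draw <- sample_gene_stat(mu, study_fx[cmp$study_accession, ], config)
    gs[[i]] <- data.frame(comparison_id = cmp$comparison_id, gene = genes,
                          draw, stringsAsFactors = FALSE)
  }
  gs <- do.call(rbind, c(gs, make.row.names = FALSE))
  truth_cls <- expand.grid(gene = genes, inducer = inducers,
                           stringsAsFactors = FALSE)
  base_mu <- planted_mean(truth_cls$gene, truth_cls$inducer, "D5_7", spec)
  early_mu <- planted_mean(truth_cls$gene, truth_cls$inducer, "D0_4", spec)
  any_mu <- ifelse(base_mu != 0, base_mu, early_mu)
  truth_cls$class <- ifelse(any_mu > 0, "up",
                            ifelse(any_mu < 0, "down", "null"))
  db <- structure(list(studies = studies, comparisons = comparisons,
                       genestats = gs[, c("comparison_id", "gene", "logFC",
                                          "p")],
                       truth = list(classes = truth_cls,
                                    outliers = gs$outlier,
                                    panel = panel)),
                  class = "senodb")
  validate_database(db)
  db
}
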