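#' Controlled vocabularies for the senescence comparison database
#'
#' The database recognises fourteen senescence-induction categories, four
#' control-cell categories, the intervention flags used by the inhibition
#' contrasts, and a fixed set of temporal bins. These vectors are the single
#' source of truth for validation throughout the package.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
INDUCER_VOCAB <- c("REP", "DDIS", "OIS", "BYS", "CR", "NBIS", "NIS", "RNIS",
                   "OSKM", "RiboMature", "dNTP", "MitoSkip", "PIIPS",
                   "Trehalose")

#' @rdname vocabularies
#' @export
CONTROL_VOCAB <- c("proliferating", "quiescent", "immortalised", "none")

#' @rdname vocabularies
#' @export
INTERVENTION_VOCAB <- c("none", "p53_inhibition", "RelA_inhibition", "other")

#' @rdname vocabularies
#' @export
TIME_UNIT_VOCAB <- c("days", "PD", "unknown")

#' Time bins used for temporal grouping of comparisons
#'
#' Non-replicative comparisons are grouped by day post-induction into five
#' closed integer-day bins (0-4, 5-7, 8-11, 12-14, 15+). Replicative (REP)
#' comparisons are split into 0-40 days and 41+ days post-induction; REP
#' times stated in population doublings, or not stated at all, fall in the
#' 0-40 group on the assumption that a deliberate long-term design would
#' state its day count. Non-REP comparisons with unknown time are UNBINNED.
#'
#' @export
TIME_BINS <- c("D0_4", "D5_7", "D8_11", "D12_14", "D15plus",
               "REP0_40", "REP41plus", "UNBINNED")
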