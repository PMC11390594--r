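#' Thresholds used by the phenotype criteria checker
#'
#' The published criteria state directions only ("higher", "decreased",
#' "later"); the quantitative margins here are package choices sized to
#' keep numerical noise from flipping qualitative claims: sustained
#' expression means at least `fold_sustained` (1.2x) of the pre-induction
#' baseline; "higher/lower than" means a ratio of at least `fold_ratio`
#' (1.1x) or at most `fold_down` (0.9x); onset crossings use
#' `fold_cross` (1.5x) of baseline; the p16 delay margin is `lag_au`
#' (2 AU) and the IL-6 onset window after the Notch switch is
#' `onset_au` (5 AU). "Expression" comparisons use trapezoidal time-means
#' over the stated windows rather than endpoint values, because the
#' claims are about sustained phenotypes.
#'
#' @param fold_sustained,fold_ratio,fold_down,fold_cross,nicd_drop
#'   Fold-change thresholds.
#' @param lag_au,onset_au Time margins in AU.
#' @return Named list of thresholds.
#' @export
criteria_config <- function(fold_sustained = 1.2, fold_ratio = 1.1,
                            fold_down = 0.9, fold_cross = 1.5,
                            nicd_drop = 0.5, lag_au = 2, onset_au = 5) {
  list(fold_sustained = fold_sustained, fold_ratio = fold_ratio,
       fold_down = fold_down, fold_cross = fold_cross,
       nicd_drop = nicd_drop, lag_au = lag_au, onset_au = onset_au)
}

first_crossing <- function(traj, species, level, after = 0) {
  tt <- traj$times[traj$times >= after]
  y <- traj_at(traj, species, tt)
  i <- which(y >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(tt[1])
  # linear interpolation between the bracketing grid points
  t0 <- tt[i - 1]; t1 <- tt[i]; y0 <- y[i - 1]; y1 <- y[i]
  unname(t0 + (level - y0) / (y1 - y0) * (t1 - t0))
}

#' Simulate the six-trajectory bundle the criteria checker consumes
#'
#' DDIS and OIS, each without knockdown and with p53 and RelA knockdowns,
#' on a shared grid.
#'
#' @param model A `"senescence_model"` (default: reference model).
#' @param kd_scale Knockdown scale factor.
#' @param times Shared output grid.
#' @return Named list of six `"trajectory"` objects
#'   (`DDIS.none`, ..., `OIS.RelA`).
#' @export
simulate_bundle <- function(model = build_reference_model(),
                            kd_scale = 0.1, times = NULL) {
  out <- list()
  for (cond in c("DDIS", "OIS")) {
    # share the pre-induction fixed point across the condition's KDs
    sched <- configure_condition(model, cond, "none")
    init <- find_steady_state(sched$model)
    for (kd in c("none", "p53", "RelA")) {
      sched <- configure_condition(model, cond, kd, kd_scale = kd_scale)
      out[[paste(cond, kd, sep = ".")]] <-
        simulate_condition(sched, times = times, init = init)
    }
  }
  out
}

criterion_descriptions <- c(
  C1 = "p21 and p16 remain expressed beyond 4 days post-induction (both conditions)",
  C2 = "higher p53 activation and p21 expression in DDIS than in OIS",
  C3 = "higher p16 expression in OIS than in DDIS",
  C4 = "p16 expression rises later in DDIS than in OIS",
  C5 = "Notch switch drops NICD and is followed promptly by the SASP onset",
  C6 = "stronger inflammatory phenotype (pNF-kB, IL-6) in OIS than in DDIS",
  C7 = "inflammatory phenotype established 5-8 days post-induction (t 65-85)",
  C8 = "more p38 phosphorylation in OIS than in DDIS",
  C9 = "p53 knockdown upregulates p16",
  C10 = "p53 knockdown decreases p21",
  C11 = "p53 knockdown upregulates p38 in DDIS",
  C12 = "RelA knockdown decreases p53 signalling (pp53, p21)")

#' Evaluate the twelve phenotype criteria on a trajectory bundle
#'
#' Each criterion is a quantitative predicate over the six simulated
#' trajectories (see [criteria_config()] for thresholds and windows):
#' sustained p21/p16 on t 60-100 versus the pre-induction baseline (C1);
#' DDIS-vs-OIS ratios of time-mean pp53/p21 (C2), p16 (C3) and pp38 (C8)
#' on t 40-100; the p16 1.5x-baseline crossing at least 2 AU later in
#' DDIS than OIS (C4); NICD(70) at most half of NICD(60) with the IL-6
#' rise onset within 5 AU of the switch (C5); OIS-vs-DDIS ratios of
#' time-mean pNF-kB/IL-6 on t 65-100 (C6); the IL-6 1.5x-baseline
#' crossing inside t 65-85 (C7); and knockdown-vs-none ratios of
#' time-means on t 60-100 for p16 (C9, up), p21 (C10, down), total p38 in
#' DDIS (C11, up) and pp53/p21 under RelA knockdown (C12, down).
#' Knockdown criteria C9, C10 and C12 must hold in both conditions; C11
#' is a DDIS statement (the OIS sub-result is reported in `details`).
#'
#' The margin is the signed relative distance to the threshold
#' (positive iff passed); for multi-part criteria it is the worst part.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param config Output of [criteria_config()].
#' @return Data frame of class `"criteria_result"`: `id`, `description`,
#'   `passed`, `margin`, plus a `details` attribute with per-condition
#'   sub-results.
#' @export
evaluate_criteria <- function(bundle, config = criteria_config()) {
  need <- as.vector(outer(c("DDIS", "OIS"), c("none", "p53", "RelA"),
                          paste, sep = "."))
  missing <- setdiff(need, names(bundle))
  if (length(missing))
    stop("missing trajectory ", missing[1],
         "; every criterion needs the full bundle")
  if (!all(vapply(bundle, `[[`, TRUE, "equilibrated")))
    stop("bundle contains a non-equilibrated trajectory")
  D <- bundle$DDIS.none; O <- bundle$OIS.none
  cfg <- config
  details <- list()
  res <- list()
  add <- function(id, margin, detail = NULL) {
    res[[id]] <<- data.frame(id = id,
                             description = criterion_descriptions[[id]],
                             passed = is.finite(margin) && margin > 0,
                             margin = margin)
    details[[id]] <<- detail
  }
  rel_above <- function(x, thr) x / thr - 1   # >0 iff x > thr
  rel_below <- function(x, thr) 1 - x / thr   # >0 iff x < thr

  # C1: sustained p21 and p16 on [60, 100] in both conditions
  m <- sapply(list(D, O), function(tr)
    sapply(c("p21", "p16"), function(sp) {
      tt <- tr$times[tr$times >= 60]
      rel_above(min(traj_at(tr, sp, tt)),
                cfg$fold_sustained * tr$baseline[sp])
    }))
  add("C1", min(m), m)

  # C2: mean pp53, p21 on [40, 100]: DDIS over OIS
  r <- sapply(c("pp53", "p21"), function(sp)
    traj_mean(D, sp, c(40, 100)) / traj_mean(O, sp, c(40, 100)))
  add("C2", min(rel_above(r, cfg$fold_ratio)), r)

  # C3: mean p16: OIS over DDIS
  r3 <- traj_mean(O, "p16", c(40, 100)) / traj_mean(D, "p16", c(40, 100))
  add("C3", rel_above(r3, cfg$fold_ratio), r3)

  # C4: p16 crosses 1.5x baseline later in DDIS
  tD <- first_crossing(D, "p16", cfg$fold_cross * D$baseline["p16"], 40)
  tO <- first_crossing(O, "p16", cfg$fold_cross * O$baseline["p16"], 40)
  lag <- tD - tO
  add("C4", if (is.na(lag)) -Inf else (lag - cfg$lag_au) / cfg$lag_au,
      c(t_DDIS = tD, t_OIS = tO))

  # C5: NICD halves across the switch; IL-6 onset within 5 AU after it
  m5 <- sapply(list(DDIS = D, OIS = O), function(tr) {
    drop <- traj_at(tr, "NICD", 70) / traj_at(tr, "NICD", 60)
    onset <- first_crossing(tr, "IL6", 1.2 * traj_at(tr, "IL6", 65), 65)
    c(nicd = rel_below(drop, cfg$nicd_drop),
      onset = if (is.na(onset)) -Inf
              else (cfg$onset_au - (onset - 65)) / cfg$onset_au)
  })
  add("C5", min(m5), m5)

  # C6: mean pNFKB, IL6 on [65, 100]: OIS over DDIS
  r6 <- sapply(c("pNFKB", "IL6"), function(sp)
    traj_mean(O, sp, c(65, 100)) / traj_mean(D, sp, c(65, 100)))
  add("C6", min(rel_above(r6, cfg$fold_ratio)), r6)

  # C7: IL-6 crosses 1.5x baseline inside [65, 85] in both conditions
  m7 <- sapply(list(DDIS = D, OIS = O), function(tr) {
    tc <- first_crossing(tr, "IL6", cfg$fold_cross * tr$baseline["IL6"],
                         40)
    if (is.na(tc)) -Inf else min(tc - 65, 85 - tc) / 20
  })
  add("C7", min(m7), m7)

  # C8: mean pp38 on [40, 100]: OIS over DDIS
  r8 <- traj_mean(O, "pp38", c(40, 100)) / traj_mean(D, "pp38", c(40, 100))
  add("C8", rel_above(r8, cfg$fold_ratio), r8)

  kd_ratio <- function(kd, sp, window = c(60, 100))
    sapply(c("DDIS", "OIS"), function(cond)
      traj_mean(bundle[[paste(cond, kd, sep = ".")]], sp, window) /
        traj_mean(bundle[[paste(cond, "none", sep = ".")]], sp, window))

  r9 <- kd_ratio("p53", "p16")
  add("C9", min(rel_above(r9, cfg$fold_ratio)), r9)
  r10 <- kd_ratio("p53", "p21")
  add("C10", min(rel_below(r10, cfg$fold_down)), r10)
  r11 <- kd_ratio("p53", c("p38", "pp38"))
  add("C11", rel_above(r11[["DDIS"]], cfg$fold_ratio), r11)
  r12a <- kd_ratio("RelA", "pp53"); r12b <- kd_ratio("RelA", "p21")
  add("C12", min(rel_below(c(r12a, r12b), cfg$fold_down)),
      rbind(pp53 = r12a, p21 = r12b))

  out <- do.call(rbind, res[paste0("C", 1:12)])
  rownames(out) <- NULL
  attr(out, "details") <- details
  class(out) <- c("criteria_result", "data.frame")
  out
}

#' @export
print.criteria_result <- function(x, ...) {
  cat(sprintf("phenotype criteria: %d/%d passed\n", sum(x$passed),
              nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-4s %-5s margin %+8.3f  %s\n", x$id[i],
                ifelse(x$passed[i], "PASS", "FAIL"), x$margin[i],
                x$description[i]))
  invisible(x)
}
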