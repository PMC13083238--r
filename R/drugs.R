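#' Classify drug mode of action
#'
#' Maps free-text action types to `"antagonistic"`, `"agonistic"` or
#' `"other"`. Antagonistic: inhibitor, antagonist, blocker, negative
#' allosteric modulator, antisense inhibitor, RNAi inhibitor, inverse agonist,
#' disrupting agent, negative modulator, degrader, allosteric antagonist.
#' Agonistic: activator, agonist, partial agonist, positive allosteric
#' modulator, positive modulator, stabilizer.
#'
#' @param action_type Character vector of action-type labels.
#' @return Character vector of classes.
#' @export
classify_action <- function(action_type) {
  antagonistic <- c("inhibitor", "antagonist", "blocker",
                    "negative allosteric modulator", "antisense inhibitor",
                    "rnai inhibitor", "inverse agonist", "disrupting agent",
                    "negative modulator", "degrader", "allosteric antagonist")
  agonistic <- c("activator", "agonist", "partial agonist",
                 "positive allosteric modulator", "positive modulator",
                 "stabilizer")
  x <- tolower(trimws(action_type))
  dplyr::case_when(x %in% antagonistic ~ "antagonistic",
                   x %in% agonistic ~ "agonistic",
                   TRUE ~ "other")
}

#' Oncology indication matcher
#'
#' Case-insensitive text match for "cancer", "neoplasia", "neoplasm",
#' "leukemia", "tumor" or any word ending in "oma" (so "melanoma" matches and,
#' by the literal rule, so does "glaucoma" unless stop-listed).
#'
#' @param indication Character vector of indication labels.
#' @param stop_list Optional words exempt from the "-oma" suffix rule.
#' @return Logical vector.
#' @export
is_oncology_indication <- function(indication, stop_list = character(0)) {
  x <- tolower(indication)
  term <- grepl("cancer|neoplasia|neoplasm|leukemia|tumor", x)
  words <- strsplit(x, "[^a-z]+")
  oma <- map_lgl(words, function(w) {
    w <- setdiff(w[endsWith(w, "oma")], tolower(stop_list))
    length(w) > 0
  })
  term | oma
}

#' Drug clinical-trial phase-transition enrichment
#'
#' Tests whether drugs whose target genes have human knockouts are more likely
#' to have transitioned past a given trial phase. The outcome is
#' `max_phase > transition_phase`; the exposure is having any (default) or all
#' target genes in the knockout catalog. The headline model is logistic
#' regression adjusting for the number of target genes; the unadjusted Fisher
#' exact OR/P on the collapsed 2x2 table is reported alongside. Stratified
#' reruns by action class and oncology flag are available through
#' [drug_transition_strata()].
#'
#' @param drugs Drug tibble (schema of [read_drug_table()]: `drug_id`,
#'   `target_genes` semicolon-separated, `max_phase` 1-4, `action_type`,
#'   `indication_class`).
#' @param catalog A [build_catalog()] result (or character vector of knockout
#'   genes).
#' @param transition_phase Phase threshold `k`; the outcome is progression
#'   past phase `k` (run for k = 1..3 to profile transitions).
#' @param exposure `"any"` or `"all"` target genes knocked out.
#' @return One-row tibble: `transition_phase`, `exposure`, `n_drugs`,
#'   `n_exposed`, logistic `or`/`p` (NA with a flag when the outcome is
#'   single-class), Fisher `or_fisher`/`p_fisher`, and the 2x2 cells.
#' @export
drug_transition_enrichment <- function(drugs, catalog, transition_phase = 1L,
                                       exposure = c("any", "all")) {
  exposure <- arg_match(exposure)
  if (!nrow(drugs)) abort("no drugs")
  ko_genes <- if (inherits(catalog, "knockout_catalog")) {
    catalog$gene_summary$gene
  } else as.character(catalog)
  targets <- strsplit(drugs$target_genes, ";", fixed = TRUE)
  n_targets <- lengths(targets)
  hit <- map_lgl(targets, function(tg) {
    if (exposure == "any") any(tg %in% ko_genes) else all(tg %in% ko_genes)
  })
  y <- as.integer(drugs$max_phase > transition_phase)
  a <- sum(hit & y == 1); b <- sum(hit & y == 0)
  c_ <- sum(!hit & y == 1); d <- sum(!hit & y == 0)
  ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
  or_fisher <- (a * d) / (b * c_)
  single_class <- length(unique(y)) < 2 || length(unique(hit)) < 2
  if (!single_class) {
    fit <- glm(y ~ hit + n_targets, family = binomial())
    sm <- summary(fit)$coefficients
    or <- exp(sm["hitTRUE", "Estimate"])
    p <- sm["hitTRUE", "Pr(>|z|)"]
  } else {
    or <- NA_real_; p <- NA_real_
  }
  tibble(transition_phase = as.integer(transition_phase), exposure = exposure,
         n_drugs = nrow(drugs), n_exposed = sum(hit),
         or = or, p = p, logistic_skipped = single_class,
         or_fisher = or_fisher, p_fisher = ft$p.value,
         ko_pass = a, ko_fail = b, noko_pass = c_, noko_fail = d)
}

#' Stratified phase-transition enrichment
#'
#' Reruns [drug_transition_enrichment()] within strata defined by the drug's
#' mode-of-action class ([classify_action()]) and oncology indication flag
#' ([is_oncology_indication()]).
#'
#' @inheritParams drug_transition_enrichment
#' @return Tibble with one row per stratum x transition phase.
#' @export
drug_transition_strata <- function(drugs, catalog, transition_phase = 1L,
                                   exposure = "any") {
  drugs <- mutate(drugs,
                  action_class = classify_action(.data$action_type),
                  oncology = is_oncology_indication(.data$indication_class))
  strata <- list(
    all = rep(TRUE, nrow(drugs)),
    antagonistic = drugs$action_class == "antagonistic",
    agonistic = drugs$action_class == "agonistic",
    oncology = drugs$oncology,
    non_oncology = !drugs$oncology)
  imap(strata, function(sel, nm) {
    if (sum(sel) < 2) return(NULL)
    res <- tryCatch(
      drug_transition_enrichment(drugs[sel, , drop = FALSE], catalog,
                                 transition_phase, exposure),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    mutate(res, stratum = nm, .before = 1)
  }) |> list_rbind()
}
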