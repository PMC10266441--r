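# Transfer learning across substrates.
#
# The mechanism is deliberately simple: the space gains one categorical task
# parameter ("sugar").  Suggestions are pinned to the task currently being
# optimized, but the surrogate keeps the task coordinate of every record, so
# histories from related substrates inform the posterior without any change
# to the optimizer itself.

#' Augment a space with a substrate task parameter
#'
#' Adds a categorical `sugar` parameter over the task labels, fixed to the
#' current task so that every suggestion carries `sugar = current`, while the
#' surrogate still sees the task dimension of ingested prior records
#' (`in_model` parameter flag).
#'
#' @param space A [reaction_space()].
#' @param tasks Character vector of task (substrate) labels.
#' @param current The task being optimized; must be among `tasks`.
#' @param name Name of the task parameter (default `"sugar"`).
#' @return A new [reaction_space()] with the task parameter appended.
#' @export
augment_with_task <- function(space, tasks, current, name = "sugar") {
  tasks <- as.character(tasks)
  if (anyDuplicated(tasks) > 0L) stop_rxn("task labels must be unique")
  if (!current %in% tasks) stop_rxn("current task '%s' not among tasks", current)
  if (name %in% names(space$params)) {
    stop_rxn("space already has a '%s' parameter", name)
  }
  task_param <- param_spec(name, "categorical", levels = tasks,
                           fixed = current, in_model = TRUE)
  reaction_space(c(space$params, setNames(list(task_param), name)),
                 metadata = space$metadata,
                 name = paste0(space$name, "+", name))
}

#' Ingest prior-task histories into an augmented space
#'
#' Validates prior experiment records against the (augmented) space, mapping
#' parent-space columns into the child space where a derivation exists:
#' a categorical `solvent` maps onto a continuous MeCN:THF `solvent_ratio`
#' (`MeCN` -> 0, `MeCN/THF` -> 0.5, `THF` -> 1) when the child space carries
#' the ratio parameter.  Records that cannot be mapped or whose values fall
#' outside the child domain are dropped, never clipped, and the kept/dropped
#' counts are reported.
#'
#' @param priors Tibble of prior records: one column per condition parameter,
#'   a task column (default `sugar`), and a `score` column (yield percent).
#'   May carry species area columns; missing ones are filled with `NA`.
#' @param space The augmented [reaction_space()] (see [augment_with_task()]).
#' @param task_col Name of the task column in `priors`.
#' @return A tibble of records with `phase = "prior"`, ready to prepend to a
#'   loop history; the ingestion report (kept/dropped counts and per-record
#'   reasons) is attached as attribute `"report"` and emitted as a message.
#' @export
ingest_prior <- function(priors, space, task_col = "sugar") {
  priors <- as_tibble(priors)
  if (!nrow(priors)) {
    return(structure(empty_history(space),
                     report = tibble(kept = 0L, dropped = 0L)))
  }
  if (!"score" %in% names(priors)) stop_rxn("priors need a 'score' column")
  if (!task_col %in% names(priors)) {
    stop_rxn("priors need a '%s' task column", task_col)
  }
  if (task_col != "sugar") priors$sugar <- priors[[task_col]]

  # Derivable column mapping: categorical solvent -> MeCN:THF ratio.
  if ("solvent_ratio" %in% names(space$params) &&
      !"solvent_ratio" %in% names(priors) && "solvent" %in% names(priors)) {
    ratio_map <- c(MeCN = 0, `MeCN/THF` = 0.5, THF = 1)
    priors$solvent_ratio <- unname(ratio_map[as.character(priors$solvent)])
  }
  missing_cols <- setdiff(names(space$params), names(priors))
  for (m in missing_cols) priors[[m]] <- NA

  chk <- check_candidates(priors, space)
  bad_score <- !is.finite(priors$score) | priors$score < 0 | priors$score > 100
  chk$ok[bad_score] <- FALSE
  chk$reason[bad_score & is.na(chk$reason)] <- "score outside [0, 100]"

  kept <- priors[chk$ok, , drop = FALSE]
  n_drop <- sum(!chk$ok)
  if (n_drop > 0L) {
    inform(sprintf("ingest_prior: dropped %d of %d prior record(s)",
                   n_drop, nrow(priors)))
  }
  rec <- validate_candidates(kept[names(space$params)], space)
  for (a in c("area_reactant", "area_mono", "area_di")) {
    rec[[a]] <- if (a %in% names(kept)) as.numeric(kept[[a]]) else NA_real_
  }
  rec$score <- as.numeric(kept$score)
  rec$phase <- "prior"
  rec$task <- as.character(kept$sugar)
  rec$seed <- NA_integer_
  rec <- dplyr::bind_cols(tibble(index = seq_len(nrow(rec))), rec)
  structure(rec,
            report = tibble(kept = nrow(rec), dropped = n_drop,
                            reasons = list(chk$reason[!chk$ok])))
}
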