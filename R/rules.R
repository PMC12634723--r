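#' Declared rule-context variables
#'
#' The measurement bundle a rulebase may reference: total phase times
#' (`tt_p`, `tt_t`), per-axis angular-velocity summaries
#' (`rot_r_p` ... `rot_y_t`), mean accelerations (`acc_x_p` ... `acc_z_t`),
#' inactivity times (`th_p`, `th_t`) and per-disc times (`d1_p` ... `d60_t`).
#' Rules referencing anything else are rejected at load time.
#'
#' @param n_discs number of per-disc slots.
#' @return character vector of variable names.
#' @export
declared_variables <- function(n_discs = 60L) {
  c("tt_p", "tt_t",
    paste0("rot_", rep(c("r", "p", "y"), each = 2), "_", c("p", "t")),
    paste0("acc_", rep(c("x", "y", "z"), each = 2), "_", c("p", "t")),
    "th_p", "th_t",
    paste0("d", rep(seq_len(n_discs), each = 2), "_", c("p", "t")))
}

rule_comparators <- c("<", ">", "<=", ">=")

# accept the unicode comparison glyphs in config documents
normalize_comparator <- function(op) {
  if (op == "≤") "<=" else if (op == "≥") ">=" else op
}

#' Default threshold set for the expert rulebase
#'
#' Total-time limits are 62 s (placing) and 67 s (turning); the lower limits
#' default to 30 s. Normal-range floors for angular velocity and
#' acceleration are derived from the packaged healthy-cohort reference
#' tables as `mean - 2 * sample sd`, floored at 0. Inactivity and per-disc
#' limits default to 10 s and 2 s. All values are plain named numbers and
#' can be changed when desired.
#'
#' @return named list of threshold values.
#' @export
default_thresholds <- function() {
  t5 <- load_fixture("table5")
  t6 <- load_fixture("table6")
  floor2 <- function(v) max(mean(v) - 2 * stats::sd(v), 0)
  th <- list(
    max_t_p = 62, min_t_p = 30, max_t_t = 67, min_t_t = 30,
    nrot_r_p = floor2(t5$roll_placing_dps), nrot_r_t = floor2(t5$roll_turning_dps),
    nrot_p_p = floor2(t5$pitch_placing_dps), nrot_p_t = floor2(t5$pitch_turning_dps),
    nrot_y_p = floor2(t5$yaw_placing_dps), nrot_y_t = floor2(t5$yaw_turning_dps),
    nacc_x_p = floor2(t6$x_placing_ms2), nacc_x_t = floor2(t6$x_turning_ms2),
    nacc_y_p = floor2(t6$y_placing_ms2), nacc_y_t = floor2(t6$y_turning_ms2),
    nacc_z_p = floor2(t6$z_placing_ms2), nacc_z_t = floor2(t6$z_turning_ms2),
    n_th_p = 10, n_th_t = 10, n_d_p = 2, n_d_t = 2
  )
  th
}

cond <- function(var, op, threshold) list(var = var, op = op, threshold = threshold)

#' The default shipped rulebase
#'
#' Contains the clinical screening rules: a "Normal" rule on the two total
#' phase times; over-time branch rules for each phase with kinematic
#' sub-rules (insufficient forearm rotation in turning, inadequate reaching
#' acceleration in placing); inactivity ("thinking time") rules; and a
#' per-disc delay family instantiated for every disc in both phases.
#' Sub-rules attached to a branch are evaluated only when the branch fires;
#' the "Normal" finding is suppressed whenever any abnormal finding fires.
#'
#' @param n_discs number of discs for the per-disc family templates.
#' @return a `rulebase` object (validated).
#' @export
default_rulebase <- function(n_discs = 60L) {
  rules <- list(
    list(id = "normal", connective = "all",
         conditions = list(cond("tt_p", "<", "max_t_p"),
                           cond("tt_p", ">", "min_t_p"),
                           cond("tt_t", "<", "max_t_t"),
                           cond("tt_t", ">", "min_t_t")),
         text = "Normal", suppressed_by_abnormal = TRUE),
    list(id = "placing_over", connective = "all",
         conditions = list(cond("tt_p", ">", "max_t_p")),
         text = NULL,
         children = list(
           list(id = "placing_low_acc", connective = "any",
                conditions = list(cond("acc_x_p", "<", "nacc_x_p"),
                                  cond("acc_y_p", "<", "nacc_y_p"),
                                  cond("acc_z_p", "<", "nacc_z_p")),
                text = "Inadequate movement in placing. Possible restriction of the elbow and/or shoulder joint."))),
    list(id = "turning_over", connective = "all",
         conditions = list(cond("tt_t", ">", "max_t_t")),
         text = NULL,
         children = list(
           list(id = "turning_low_rotation", connective = "all",
                conditions = list(cond("rot_r_t", "<", "nrot_r_t")),
                text = "Insufficient rotation in turning. Possible restriction of pro-sup."))),
    list(id = "thinking_placing", connective = "all",
         conditions = list(cond("th_p", ">", "n_th_p")),
         text = "High inactive waiting time."),
    list(id = "thinking_turning", connective = "all",
         conditions = list(cond("th_t", ">", "n_th_t")),
         text = "High inactive waiting time."),
    list(id = "disc_delay_placing", connective = "all",
         foreach = list(from = 1L, to = n_discs),
         conditions = list(cond("d{i}_p", ">", "n_d_p")),
         text = "Delay in placing on disc {i}."),
    list(id = "disc_delay_turning", connective = "all",
         foreach = list(from = 1L, to = n_discs),
         conditions = list(cond("d{i}_t", ">", "n_d_t")),
         text = "Delay in turning on disc {i}.")
  )
  validate_rulebase(list(rules = rules), n_discs = n_discs)
}

expand_templates <- function(rules) {
  out <- list()
  for (r in rules) {
    if (!is.null(r$foreach)) {
      for (i in seq.int(r$foreach$from, r$foreach$to)) {
        ri <- r
        ri$foreach <- NULL
        ri$id <- paste0(r$id, "_", i)
        ri$conditions <- lapply(r$conditions, function(cc) {
          cc$var <- gsub("{i}", i, cc$var, fixed = TRUE)
          cc
        })
        if (!is.null(r$text)) ri$text <- gsub("{i}", i, r$text, fixed = TRUE)
        out[[length(out) + 1L]] <- ri
      }
    } else {
      if (!is.null(r$children)) r$children <- expand_templates(r$children)
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

validate_rules <- function(rules, vars, path = "rules") {
  ids <- character(0)
  walk <- function(rs) {
    for (r in rs) {
      if (is.null(r$id)) stop("rule without id")
      if (r$id %in% ids) stop(sprintf("duplicate rule id '%s'", r$id))
      ids <<- c(ids, r$id)
      conn <- r$connective %||% "all"
      if (!conn %in% c("all", "any"))
        stop(sprintf("rule '%s': unknown connective '%s'", r$id, conn))
      for (cc in r$conditions) {
        if (!cc$op %in% rule_comparators)
          stop(sprintf("rule '%s': unknown comparator '%s'", r$id, cc$op))
        if (!cc$var %in% vars)
          stop(sprintf("rule '%s': undeclared variable '%s'", r$id, cc$var))
      }
      if (!is.null(r$children)) walk(r$children)
    }
  }
  walk(rules)
  invisible(TRUE)
}

normalize_ops <- function(rules) {
  lapply(rules, function(r) {
    r$conditions <- lapply(r$conditions, function(cc) {
      cc$op <- normalize_comparator(cc$op)
      cc
    })
    if (!is.null(r$children)) r$children <- normalize_ops(r$children)
    r
  })
}

#' Validate a rulebase document
#'
#' Expands per-disc templates (`foreach` with a `{i}` placeholder) and
#' checks rule ids for uniqueness, comparators against `<, >, <=, >=` (the
#' unicode glyphs are accepted and normalized) and condition variables
#' against [declared_variables()]. Errors are raised at load, never at
#' evaluation.
#'
#' @param doc list with a `rules` element.
#' @param n_discs declared per-disc variable slots.
#' @return a validated `rulebase` object.
#' @export
validate_rulebase <- function(doc, n_discs = 60L) {
  rules <- normalize_ops(expand_templates(doc$rules))
  validate_rules(rules, declared_variables(n_discs))
  structure(list(rules = rules), class = "rulebase")
}

#' @export
print.rulebase <- function(x, ...) {
  n_top <- length(x$rules)
  n_all <- n_top + sum(vapply(x$rules, function(r) length(r$children %||% list()), 1L))
  cat(sprintf("<rulebase> %d top-level rules (%d incl. sub-rules)\n", n_top, n_all))
  invisible(x)
}

#' Load / write a rulebase as JSON
#'
#' A serialize-then-load round trip preserves rule order, conditions and
#' texts exactly. Validation happens at load.
#'
#' @param path file path.
#' @param n_discs declared per-disc variable slots.
#' @export
load_rulebase <- function(path, n_discs = 60L) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_rulebase(doc, n_discs = n_discs)
}

#' @rdname load_rulebase
#' @param rb a `rulebase` object.
#' @export
write_rulebase <- function(rb, path) {
  jsonlite::write_json(list(rules = rb$rules), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

compare_op <- function(x, op, y) {
  switch(op, "<" = x < y, ">" = x > y, "<=" = x <= y, ">=" = x >= y)
}

rule_fires <- function(r, ctx, thresholds) {
  conn <- r$connective %||% "all"
  vals <- vapply(r$conditions, function(cc) {
    x <- ctx[[cc$var]]
    th <- thresholds[[cc$threshold]]
    if (is.null(x) || is.null(th) || is.na(x)) return(NA)
    compare_op(x, cc$op, th)
  }, logical(1))
  if (any(is.na(vals))) {
    # conditions on missing measurements cannot hold
    vals[is.na(vals)] <- FALSE
  }
  if (conn == "all") all(vals) else any(vals)
}

#' Evaluate a rulebase over a measurement context
#'
#' Every rule whose conditions hold over `ctx` fires, in declaration order;
#' sub-rules are evaluated only when their parent branch fires. Conditions
#' on missing measurements evaluate false. Rules flagged
#' `suppressed_by_abnormal` (the "Normal" rule) are dropped when any other
#' finding fires. Evaluation is a pure function of its arguments.
#'
#' @param ctx named list of measured variables (see [declared_variables()]).
#' @param thresholds named list of threshold values
#'   (see [default_thresholds()]).
#' @param rulebase a validated `rulebase`.
#' @return data.frame of findings with columns `id`, `text`, in firing order.
#' @export
evaluate_rules <- function(ctx, thresholds = default_thresholds(),
                           rulebase = default_rulebase()) {
  findings <- data.frame(id = character(0), text = character(0))
  suppressed <- character(0)
  emit <- function(r) {
    if (!is.null(r$text))
      findings <<- rbind(findings, data.frame(id = r$id, text = r$text))
    if (isTRUE(r$suppressed_by_abnormal)) suppressed <<- c(suppressed, r$id)
  }
  walk <- function(rs) {
    for (r in rs) {
      if (rule_fires(r, ctx, thresholds)) {
        emit(r)
        if (!is.null(r$children)) walk(r$children)
      }
    }
  }
  walk(rulebase$rules)
  if (length(suppressed) && any(!(findings$id %in% suppressed)))
    findings <- findings[!(findings$id %in% suppressed), , drop = FALSE]
  rownames(findings) <- NULL
  findings
}

#' Build a rule context from pipeline outputs
#'
#' Collects total phase times, per-disc durations, angular-velocity and
#' acceleration summaries and inactivity times into the flat variable
#' bundle the rulebase evaluates. Any component may be NULL (its variables
#' are then absent and rules referencing them do not fire).
#'
#' @param placing,turning lists with optional elements `total` (s),
#'   `durations` (per-disc s), `kin` (a `kin_summary`), `inactivity` (s).
#' @return named list of rule variables.
#' @export
rule_context <- function(placing = NULL, turning = NULL) {
  ctx <- list()
  add_phase <- function(ph, suf) {
    if (is.null(ph)) return()
    if (!is.null(ph$total)) ctx[[paste0("tt_", suf)]] <<- ph$total
    if (!is.null(ph$durations)) {
      for (i in seq_along(ph$durations))
        ctx[[paste0("d", i, "_", suf)]] <<- ph$durations[i]
    }
    if (!is.null(ph$kin)) {
      g <- ph$kin$gyro_max_abs
      ctx[[paste0("rot_r_", suf)]] <<- unname(g["roll"])
      ctx[[paste0("rot_p_", suf)]] <<- unname(g["pitch"])
      ctx[[paste0("rot_y_", suf)]] <<- unname(g["yaw"])
      a <- ph$kin$accel_peak_mean
      ctx[[paste0("acc_x_", suf)]] <<- unname(a["x"])
      ctx[[paste0("acc_y_", suf)]] <<- unname(a["y"])
      ctx[[paste0("acc_z_", suf)]] <<- unname(a["z"])
    }
    if (!is.null(ph$inactivity)) ctx[[paste0("th_", suf)]] <<- ph$inactivity
  }
  add_phase(placing, "p")
  add_phase(turning, "t")
  ctx
}
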