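#' Event tables for joint recurrent/terminal gap-time data
#'
#' An event table holds one row per observed gap per subject, in long format.
#' The reserved columns are `subject_id`, `gap_index`, `gap_time`,
#' `recurrent_event` and `death_event`; every remaining numeric column is
#' treated as a subject-level covariate (constant within subject). The final
#' gap of a subject carries the death indicator; a death and a recurrent
#' event can never be flagged on the same row, because a recurrent event
#' always opens a new gap while death terminates the subject's follow-up.
#'
#' @param data a data.frame with the reserved columns above plus zero or
#'   more numeric covariate columns.
#' @return an object of class `jf_event_table`: the input sorted by
#'   `(subject_id, gap_index)`, with attribute `covariates` naming the
#'   covariate columns.
#' @examples
#' tab <- event_table(data.frame(
#'   subject_id = c("a", "a", "b"), gap_index = c(1, 2, 1),
#'   gap_time = c(100, 50, 200), recurrent_event = c(1, 0, 0),
#'   death_event = c(0, 0, 1), age = c(61, 61, 70)))
#' censoring_summary(tab)
#' @export
event_table <- function(data) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(jf_reserved_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$subject_id <- as.character(data$subject_id)
  data <- data[order(data$subject_id, data$gap_index), , drop = FALSE]
  rownames(data) <- NULL
  covariates <- setdiff(names(data), jf_reserved_columns())
  non_num <- covariates[!vapply(data[covariates], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop("format error: covariate column(s) not numeric: ",
         paste(non_num, collapse = ", "), call. = FALSE)
  }
  out <- structure(data, covariates = covariates,
                   class = c("jf_event_table", "data.frame"))
  rep <- validate_event_table(out)
  if (!rep$ok) {
    v <- rep$violations[1, ]
    stop("validation error: ", v$rule, " (subject ", v$subject_id, "): ",
         v$message, if (nrow(rep$violations) > 1)
           paste0(" [and ", nrow(rep$violations) - 1, " more violation(s)]"),
         call. = FALSE)
  }
  out
}

jf_reserved_columns <- function() {
  c("subject_id", "gap_index", "gap_time", "recurrent_event", "death_event")
}

#' Read or write an event table as CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a header row. Reserved
#' columns are as in [event_table()]; all other numeric columns are read as
#' covariates in header order. Reading validates every table invariant and
#' fails with the violated rule and offending subject.
#'
#' @param path path to a CSV file.
#' @return [read_event_table()]: a validated `jf_event_table`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  event_table(df)
}

#' @rdname read_event_table
#' @param table a `jf_event_table`.
#' @return [write_event_table()]: `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "jf_event_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an event table without raising
#'
#' Checks every invariant of the event-table contract and reports all
#' violations (not just the first). Each invariant maps to one named rule:
#' `"nonpositive gap time"`, `"bad gap index"`, `"nonbinary indicator"`,
#' `"conflicting indicators"`, `"death before final gap"`,
#' `"missing covariate"`, `"non-constant covariate"`.
#'
#' @param table a data.frame shaped like an event table (it need not be a
#'   valid `jf_event_table` yet).
#' @return a list of class `jf_validation` with elements `ok` (logical) and
#'   `violations` (data.frame with columns `rule`, `subject_id`, `message`).
#' @export
validate_event_table <- function(table) {
  v <- list()
  add <- function(rule, subject, message) {
    v[[length(v) + 1]] <<- data.frame(rule = rule, subject_id = subject,
                                      message = message)
  }
  covariates <- attr(table, "covariates")
  if (is.null(covariates)) {
    covariates <- setdiff(names(table), jf_reserved_columns())
    covariates <- covariates[vapply(table[covariates], is.numeric, logical(1))]
  }

  bad_t <- which(!is.finite(table$gap_time) | table$gap_time <= 0)
  for (i in bad_t) {
    add("nonpositive gap time", table$subject_id[i],
        sprintf("gap_time = %s at gap_index %s", table$gap_time[i],
                table$gap_index[i]))
  }
  for (ind in c("recurrent_event", "death_event")) {
    bad <- which(!table[[ind]] %in% c(0, 1))
    for (i in bad) {
      add("nonbinary indicator", table$subject_id[i],
          sprintf("%s = %s at gap_index %s", ind, table[[ind]][i],
                  table$gap_index[i]))
    }
  }
  both <- which(table$recurrent_event == 1 & table$death_event == 1)
  for (i in both) {
    add("conflicting indicators", table$subject_id[i],
        sprintf("recurrent_event and death_event both 1 at gap_index %s",
                table$gap_index[i]))
  }

  by_subj <- split(seq_len(nrow(table)), table$subject_id)
  for (sid in names(by_subj)) {
    idx <- by_subj[[sid]]
    gi <- sort(table$gap_index[idx])
    if (!identical(as.integer(gi), seq_along(idx))) {
      add("bad gap index", sid,
          sprintf("gap_index values {%s} are not 1..%d",
                  paste(gi, collapse = ","), length(idx)))
    }
    dth <- idx[table$death_event[idx] == 1]
    last <- idx[which.max(table$gap_index[idx])]
    if (length(dth) > 0 && any(dth != last)) {
      add("death before final gap", sid,
          "death_event = 1 on a gap that is not the subject's last")
    }
    for (cv in covariates) {
      vals <- table[[cv]][idx]
      if (anyNA(vals)) {
        add("missing covariate", sid, sprintf("covariate %s has NA", cv))
      } else if (length(unique(vals)) > 1) {
        add("non-constant covariate", sid,
            sprintf("covariate %s varies within subject", cv))
      }
    }
  }
  violations <- if (length(v) == 0) {
    data.frame(rule = character(), subject_id = character(),
               message = character())
  } else {
    do.call(rbind, v)
  }
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "jf_validation")
}

#' @export
print.jf_validation <- function(x, ...) {
  if (x$ok) {
    cat("event table OK\n")
  } else {
    cat("event table INVALID:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] subject %s: %s\n", x$violations$rule[i],
                  x$violations$subject_id[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

#' Build design matrices for the joint model
#'
#' Constructs the fixed-effect design matrices `X1` and `X2` (one row per
#' gap, for the recurrent and terminal submodels respectively) and the
#' frailty incidence matrices `Z1` and `Z2` mapping subjects to gap rows.
#' Both hazards are on the gap-time (renewal) scale, so every gap is an
#' exposure interval for both processes and the two designs have N rows;
#' the recurrent and terminal submodels may select different covariate
#' columns. The subject ordering is the canonical sort of `subject_id`;
#' column `j` of `Z1` (= `Z2`) has `n_j` ones.
#'
#' @param table a validated `jf_event_table`.
#' @param covariates_recurrent,covariates_terminal optional character vectors
#'   selecting the covariates entering each submodel (default: all covariate
#'   columns, in header order).
#' @return a list of class `jf_design` with elements `X1` (N x p1), `X2`
#'   (N x p2), `Z1`, `Z2` (N x M subject incidence), `subjects`,
#'   `subject_index` (length-N map of rows to subjects), `final_rows` (row
#'   indices of each subject's last gap), `n_j`, `N`, `M`.
#' @export
build_design <- function(table, covariates_recurrent = NULL,
                         covariates_terminal = NULL) {
  stopifnot(inherits(table, "jf_event_table"))
  if (nrow(table) == 0) stop("empty event table", call. = FALSE)
  covariates <- attr(table, "covariates")
  pick <- function(sel, what) {
    if (is.null(sel)) return(covariates)
    bad <- setdiff(sel, covariates)
    if (length(bad) > 0) {
      stop("unknown ", what, " covariate(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    sel
  }
  cov1 <- pick(covariates_recurrent, "recurrent")
  cov2 <- pick(covariates_terminal, "terminal")

  subjects <- sort(unique(table$subject_id))
  M <- length(subjects)
  N <- nrow(table)
  subject_index <- match(table$subject_id, subjects)
  n_j <- tabulate(subject_index, nbins = M)
  # table is sorted by (subject_id, gap_index); last row per subject
  final_rows <- cumsum(n_j)

  as_mat <- function(cols, rows) {
    m <- as.matrix(as.data.frame(table)[rows, cols, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(NULL, cols)
    m
  }
  X1 <- as_mat(cov1, seq_len(N))
  X2 <- as_mat(cov2, seq_len(N))
  Z1 <- matrix(0, N, M)
  Z1[cbind(seq_len(N), subject_index)] <- 1
  structure(list(X1 = X1, X2 = X2, Z1 = Z1, Z2 = Z1,
                 subjects = subjects, subject_index = subject_index,
                 final_rows = final_rows, n_j = n_j, N = N, M = M),
            class = "jf_design")
}

#' Summarize censoring and event counts of an event table
#'
#' @param table a validated `jf_event_table`.
#' @return a list with `death_censoring_proportion` (fraction of subjects
#'   whose terminal indicator is censored, i.e. no death observed) and
#'   `recurrent_event_counts` (a table of the per-subject number of observed
#'   recurrent events).
#' @export
censoring_summary <- function(table) {
  stopifnot(inherits(table, "jf_event_table"))
  deaths <- tapply(table$death_event, table$subject_id, max)
  nev <- tapply(table$recurrent_event, table$subject_id, sum)
  list(death_censoring_proportion = mean(deaths == 0),
       recurrent_event_counts = table(factor(nev, levels = 0:max(nev))))
}
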