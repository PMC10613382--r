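# Rule table driving PIM (potentially inappropriate medication) detection.
#
# Each rule links a diagnosis code to drug classes that are indicated
# (their absence over the year is under-prescribing) and classes that are
# contraindicated (their prescription is over-prescribing). The engine is
# content-agnostic: the shipped demonstration table illustrates the schema,
# it is not a clinical reference.

#' Construct a PIM rule table
#'
#' @param rules data frame with columns `diagnosis`, `indicated`,
#'   `contraindicated`; the latter two are `;`-separated drug-class sets
#'   (empty string for none).
#' @param scoring_mode `"per_encounter"` (default: each encounter at which a
#'   contraindicated class is prescribed counts) or `"per_year"` (each
#'   contraindicated class counts at most once per year).
#' @return a `pim_rules` object.
#' @export
pim_rules <- function(rules, scoring_mode = c("per_encounter", "per_year")) {
  scoring_mode <- match.arg(scoring_mode)
  need <- c("diagnosis", "indicated", "contraindicated")
  missing <- setdiff(need, names(rules))
  if (length(missing) > 0)
    stop("rule table is missing column(s): ", paste(missing, collapse = ", "))
  rules <- rules[need]
  for (col in need) rules[[col]] <- as.character(rules[[col]])
  rules$indicated[is.na(rules$indicated)] <- ""
  rules$contraindicated[is.na(rules$contraindicated)] <- ""
  if (anyDuplicated(rules$diagnosis))
    stop("duplicate diagnosis codes in rule table")
  split_classes <- function(s) {
    out <- strsplit(s, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  ind <- split_classes(rules$indicated)
  con <- split_classes(rules$contraindicated)
  for (i in seq_len(nrow(rules))) {
    both <- intersect(ind[[i]], con[[i]])
    if (length(both) > 0)
      stop(sprintf("rule '%s': class '%s' is both indicated and contraindicated",
                   rules$diagnosis[i], both[1]))
  }
  structure(list(rules = rules, indicated = ind, contraindicated = con,
                 scoring_mode = scoring_mode),
            class = "pim_rules")
}

#' @export
print.pim_rules <- function(x, ...) {
  cat(sprintf("<pim_rules> %d rules, scoring mode: %s\n",
              nrow(x$rules), x$scoring_mode))
  invisible(x)
}

# Long (diagnosis, class) pairs for one role.
rules_long <- function(rules, role = c("indicated", "contraindicated")) {
  role <- match.arg(role)
  lst <- rules[[role]]
  data.frame(diagnosis = rep(rules$rules$diagnosis, lengths(lst)),
             drug_class = unlist(lst) %||% character(),
             stringsAsFactors = FALSE)
}

#' Read / write a PIM rule table as CSV
#'
#' @param path CSV file with columns `diagnosis`, `indicated`,
#'   `contraindicated` (`;`-separated class sets).
#' @param scoring_mode passed to [pim_rules()].
#' @return a `pim_rules` object.
#' @export
read_pim_rules <- function(path, scoring_mode = c("per_encounter", "per_year")) {
  pim_rules(read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                     na.strings = NULL),
            scoring_mode = match.arg(scoring_mode))
}

#' @rdname read_pim_rules
#' @param x a `pim_rules` object.
#' @export
write_pim_rules <- function(x, path) {
  stopifnot(inherits(x, "pim_rules"))
  write.csv(x$rules, path, row.names = FALSE)
  invisible(path)
}

#' Demonstration PIM rule table
#'
#' A ~15-rule demonstration table shipped with the package
#' (`inst/extdata/pim_rules_demo.csv`). Diagnosis codes are disjoint from the
#' Charlson condition codes, and no drug class appears as indicated in one
#' rule and contraindicated in another, so synthetic datasets built on this
#' table have exactly reconstructible PIM scores. It illustrates the rule
#' schema only and carries no clinical authority.
#'
#' @param scoring_mode passed to [pim_rules()].
#' @return a `pim_rules` object.
#' @export
default_pim_rules <- function(scoring_mode = c("per_encounter", "per_year")) {
  path <- system.file("extdata", "pim_rules_demo.csv", package = "pimnet",
                      mustWork = TRUE)
  read_pim_rules(path, scoring_mode = match.arg(scoring_mode))
}

# All drug classes named anywhere in a rule table.
rule_classes <- function(rules) {
  unique(c(unlist(rules$indicated), unlist(rules$contraindicated)))
}
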