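#' Construct a set of CAPS marker calls
#'
#' @param marker_id Marker identifier.
#' @param target_class Phenotype class the marker diagnoses.
#' @param positive_genotype Digestion state (`"cut"` or `"uncut"`) expected
#'   for accessions of the target class.
#' @param calls Tibble with columns `accession` and `call`
#'   (`"cut"`, `"uncut"` or `"missing"`), at least one row.
#' @return A `marker_calls` object.
#' @export
marker_calls <- function(marker_id, target_class, positive_genotype, calls) {
  if (!positive_genotype %in% c("cut", "uncut")) {
    abort("`positive_genotype` must be \"cut\" or \"uncut\".")
  }
  stopifnot(all(c("accession", "call") %in% names(calls)), nrow(calls) >= 1)
  bad <- setdiff(unique(calls$call), c("cut", "uncut", "missing"))
  if (length(bad) > 0) {
    abort(paste0("Invalid call state(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      marker_id = marker_id,
      target_class = target_class,
      positive_genotype = positive_genotype,
      calls = as_tibble(calls)
    ),
    class = "marker_calls"
  )
}

#' @method print marker_calls
#' @export
print.marker_calls <- function(x, ...) {
  cat(
    "<marker_calls> ", x$marker_id, " (", x$target_class,
    "; positive = ", x$positive_genotype, "), ",
    nrow(x$calls), " accessions\n",
    sep = ""
  )
  invisible(x)
}

score_concordance <- function(marker_id, target_class, positive, calls,
                              phenotypes, rule = NA_character_) {
  merged <- left_join(calls, phenotypes, by = "accession")
  if (anyNA(merged$class)) {
    abort(paste0(
      "Accession(s) without a phenotype: ",
      paste(merged$accession[is.na(merged$class)], collapse = ", ")
    ))
  }
  n_total <- nrow(merged)
  missing <- merged$call == "missing"
  n_missing <- sum(missing)
  if (n_missing == n_total) {
    abort("All calls are missing; match rate is undefined.")
  }
  scored <- merged[!missing, ]
  is_pos <- scored$call == positive
  is_class <- scored$class == target_class
  n_match <- sum(is_pos == is_class)
  tibble(
    marker_id = marker_id,
    target_class = target_class,
    rule = rule,
    n_total = n_total,
    n_missing = n_missing,
    n_match = n_match,
    match_rate = n_match / (n_total - n_missing)
  )
}

#' Marker-phenotype co-segregation match rate
#'
#' An accession matches iff its marker state agrees with its phenotype in
#' both directions: positive marker call together with the target-class
#' phenotype, or negative call together with any other class (two-sided
#' concordance over all surveyed lines). Missing calls are excluded from
#' numerator and denominator.
#'
#' @param marker A [marker_calls()] object.
#' @param phenotypes Tibble with `accession` and `class` covering every
#'   called accession.
#' @return One-row tibble: `marker_id`, `target_class`, `rule` (`NA` for a
#'   single marker), `n_total`, `n_missing`, `n_match` and
#'   `match_rate = n_match / (n_total - n_missing)`.
#' @export
match_rate <- function(marker, phenotypes) {
  stopifnot(inherits(marker, "marker_calls"))
  score_concordance(
    marker$marker_id, marker$target_class, marker$positive_genotype,
    marker$calls, phenotypes
  )
}

#' Joint match rate of several markers for the same class
#'
#' Combines per-marker positive indicators into one joint call per accession
#' under the chosen rule — `OR` (positive if any marker is positive, the
#' default), `AND` (all markers positive) or `majority` — and scores the
#' joint call against the phenotype as in [match_rate()]. Accessions with a
#' missing call on any marker are treated as missing for the joint marker.
#' The rule used is always reported.
#'
#' @param markers List of two or more [marker_calls()] objects sharing one
#'   `target_class`.
#' @param phenotypes Tibble with `accession` and `class`.
#' @param rule Combination rule: `"OR"`, `"AND"` or `"majority"`.
#' @return One-row tibble as in [match_rate()], with `marker_id` the `+`
#'   concatenation of the member markers and `rule` set.
#' @export
joint_match_rate <- function(markers, phenotypes,
                             rule = c("OR", "AND", "majority")) {
  rule <- match.arg(rule)
  if (length(markers) < 2) abort("Need at least two markers for a joint rate.")
  stopifnot(all(vapply(markers, inherits, logical(1), "marker_calls")))
  classes <- unique(vapply(markers, function(m) m$target_class, character(1)))
  if (length(classes) != 1) {
    abort("All markers in a joint rate must share one target class.")
  }
  pos_tbl <- purrr::map_dfr(markers, function(m) {
    m$calls |>
      mutate(
        marker_id = m$marker_id,
        state = dplyr::case_when(
          .data$call == "missing" ~ NA,
          .data$call == m$positive_genotype ~ TRUE,
          TRUE ~ FALSE
        )
      ) |>
      select("accession", "marker_id", "state")
  })
  joint <- pos_tbl |>
    group_by(.data$accession) |>
    summarise(
      any_missing = anyNA(.data$state),
      positive = switch(
        rule,
        OR = any(stats::na.omit(.data$state)),
        AND = all(stats::na.omit(.data$state)),
        majority = mean(stats::na.omit(.data$state)) > 0.5
      )
    ) |>
    mutate(call = dplyr::case_when(
      .data$any_missing ~ "missing",
      .data$positive ~ "positive",
      TRUE ~ "negative"
    ))
  score_concordance(
    paste(vapply(markers, function(m) m$marker_id, character(1)),
          collapse = "+"),
    classes,
    "positive",
    joint |> select("accession", "call"),
    phenotypes,
    rule = rule
  )
}
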