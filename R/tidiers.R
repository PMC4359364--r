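# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CenH3 survey
#'
#' @param x A `cenh3_survey` from [run_survey()].
#' @param ... Unused.
#' @return The per-species call tibble, joined with the generator truth
#'   when the survey was synthetic.
#' @export
tidy.cenh3_survey <- function(x, ...) {
  out <- x$calls
  if (nrow(x$truth)) out <- dplyr::left_join(out, x$truth, by = "species_id")
  out
}

#' Summarise a CenH3 survey in one row
#'
#' Accuracy compares the call (`present`/`absent`) with whether the
#' generator actually emitted a host CenH3 transcript into the assembly;
#' inconclusive calls count as errors against a definite truth.  A
#' "false absent" is an absent call for a species whose assembly did
#' contain a host CenH3 transcript.
#'
#' @param x A `cenh3_survey`.
#' @param ... Unused.
#' @return A one-row tibble: `n_species`, `accuracy`, `n_false_absent`,
#'   `n_inconclusive`, `mean_coverage`.
#' @export
glance.cenh3_survey <- function(x, ...) {
  acc <- NA_real_
  n_false_absent <- NA_integer_
  if (nrow(x$truth)) {
    j <- dplyr::left_join(x$calls, x$truth, by = "species_id")
    expected <- ifelse(j$cenh3_emitted, "present", "absent")
    acc <- mean(j$status == expected)
    n_false_absent <- sum(j$status == "absent" & j$cenh3_emitted)
  }
  tibble::tibble(
    n_species = nrow(x$calls),
    accuracy = acc,
    n_false_absent = n_false_absent,
    n_inconclusive = sum(x$calls$status == "inconclusive"),
    mean_coverage = mean(x$calls$coverage_fraction, na.rm = TRUE)
  )
}

#' Tidy a coverage report
#'
#' @param x A `coverage_report` from [coverage_fraction()].
#' @param ... Unused.
#' @return The per-protein recovery indicator tibble.
#' @export
tidy.coverage_report <- function(x, ...) {
  attr(x, "per_protein")
}

#' @rdname tidy.coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a bootstrapped histone tree
#'
#' @param x A `histone_tree` from [build_tree()].
#' @param ... Unused.
#' @return A tibble of edges: `parent`, `node`, `length`, `tip_label`
#'   (NA for internal nodes).
#' @export
tidy.histone_tree <- function(x, ...) {
  phy <- x$tree
  tibble::tibble(
    parent = phy$edge[, 1],
    node = phy$edge[, 2],
    length = phy$edge.length,
    tip_label = ifelse(phy$edge[, 2] <= length(phy$tip.label),
                       phy$tip.label[phy$edge[, 2]], NA_character_)
  )
}
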