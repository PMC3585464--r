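# broom-style tidiers and ggplot2 autoplot methods, plus the TSV/JSON export
# interface for solutions and numeric results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state solution into a quantity table
#'
#' @param x a `steady_state_solution`.
#' @param ... unused.
#' @return tibble with one row per model quantity: `quantity`, `kind`
#'   (species/rate), `class` (`P`, `independent-Y`, `dependent-Y`), and the
#'   steady-state `expression` in the independent quantities.
#' @exportS3Method generics::tidy
tidy.steady_state_solution <- function(x, ...) {
  qs <- quantities(x$model)
  tibble::tibble(
    quantity = qs,
    kind = ifelse(qs %in% x$model$species, "species", "rate"),
    class = dplyr::case_when(
      qs %in% x$phi$P ~ "P",
      qs %in% x$independents ~ "independent-Y",
      TRUE ~ "dependent-Y"),
    expression = vapply(qs, function(q_) rf_deparse(x$sigma[[q_]]),
                        character(1)))
}

#' @exportS3Method generics::tidy
tidy.steady_state_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$branches, function(b) {
    dplyr::mutate(tidy(b), branch = b$branch_id, .before = 1)
  }))
}

#' One-line summary of a steady-state derivation
#'
#' @param x a `steady_state_result`.
#' @param ... unused.
#' @return tibble with model size, rank, nullity, counts of independent and
#'   dependent quantities, branch and pseudospecies counts, and whether every
#'   branch passed residual verification.
#' @exportS3Method generics::glance
glance.steady_state_result <- function(x, ...) {
  b1 <- x$branches[[1]]
  tibble::tibble(
    n_species = length(x$model$species),
    n_reactions = length(x$model$reactions),
    rank = x$system$rank,
    nullity = x$system$q,
    n_independent = length(b1$independents),
    n_dependent = length(b1$dependents),
    n_pseudospecies = length(x$phi$pseudospecies),
    n_branches = length(x$branches),
    verified = all(vapply(x$branches, `[[`, logical(1), "verified")))
}

#' @exportS3Method generics::tidy
tidy.king_altman_result <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    n_patterns = vapply(x$patterns, length, integer(1)),
    minor = vapply(x$minors, rf_deparse, character(1)),
    concentration = vapply(x$concentrations, rf_deparse, character(1)))
}

#' @exportS3Method generics::tidy
tidy.ma_trajectories <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "species", values_to = "value")
}

#' Plot simulated trajectories
#'
#' @param object an `ma_trajectories` tibble from [simulate_perturbation()].
#' @param species optional subset of species to show.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ma_trajectories <- function(object, species = NULL, ...) {
  long <- tidy.ma_trajectories(object)
  if (!is.null(species)) long <- dplyr::filter(long, .data$species %in% !!species)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "abundance / concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot normalized sensitivity coefficients
#'
#' @param object an `ma_sensitivity` tibble from
#'   [sensitivity_coefficients()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ma_sensitivity <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$coefficient)
  df$quantity <- factor(df$quantity, levels = df$quantity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$coefficient)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "normalized sensitivity") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Export a steady-state solution
#'
#' Writes the quantity table of [tidy.steady_state_solution()] as TSV, and
#' optionally a machine-readable JSON dump of the expressions (including the
#' branch's quadratic record when present).
#'
#' @param solution a `steady_state_solution`.
#' @param tsv path for the TSV table.
#' @param json optional path for the JSON expression dump.
#' @return the tidy table, invisibly.
#' @export
export_solution <- function(solution, tsv, json = NULL) {
  tab <- tidy(solution)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    dump <- list(
      branch = solution$branch_id,
      independents = solution$independents,
      expressions = stats::setNames(
        lapply(names(solution$sigma), function(q_)
          rf_deparse(solution$sigma[[q_]])), names(solution$sigma)))
    if (!is.null(solution$quad)) {
      dump$quadratic <- list(u = solution$quad$u,
                             a = rf_deparse(solution$quad$a),
                             b = rf_deparse(solution$quad$b),
                             c = rf_deparse(solution$quad$c),
                             sign = solution$quad$sign)
    }
    jsonlite::write_json(dump, json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tab)
}
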