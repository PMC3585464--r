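# Built-in models: the open Michaelis-Menten variants, the fumarase
# mechanism, a desk-scale switch for threshold analysis, a random
# first-order model generator, and the xEARM loader/validator.

OMM_DOC <- "
# open Michaelis-Menten system: enzyme catalysis with substrate synthesis
# and product degradation, so a non-trivial steady state exists
E + S -> ES ; k1
ES -> E + S ; k2
ES -> E + P ; k3
Ø -> S ; k4
P -> Ø ; k5
"

OMM4_DOC <- "
# open Michaelis-Menten variant with catalysis proportional to the square of
# the enzyme-substrate complex
E + S -> ES ; k1
ES -> E + S ; k2
ES -> E + P ; k3 ; order(ES) = 2
Ø -> S ; k4
P -> Ø ; k5
"

FUMARASE_DOC <- "
# Hansen mechanism for malate synthesis by fumarase: the enzyme binds
# fumarate (F) and hydrogen (H) in either order, then hydroxyl (OH),
# followed by reversible formation of malate (M). All steps reversible.
species: E EF EH EFH EM F H OH M
E + F <-> EF    ; a1, d1
E + H <-> EH    ; a2, d2
EF + H <-> EFH  ; a3, d3
EH + F <-> EFH  ; a4, d4
EFH + OH <-> EM ; a5, d5
EM <-> E + M    ; d6, a6
"

TOY_SWITCH_DOC <- "
# two-species positive-feedback switch: signal S drives autocatalytic
# production of A (second order in A), with first-order decay and a
# third-order sink that bounds the induced state
Ø -> S ; ks
S -> Ø ; kds
Ø -> A ; k0
S + A -> S + 2 A ; kf ; order(A) = 2
A -> Ø ; kda
3 A -> 2 A ; kc
"

FUM_ENZYMES <- c("E", "EF", "EH", "EFH", "EM")
FUM_SUBSTRATES <- c("F", "H", "OH", "M")

#' Built-in model fixtures with their partition strategies
#'
#' Returns one of the packaged models together with the partition that its
#' derivation strategy uses:
#' \describe{
#'   \item{omm1}{open Michaelis-Menten, homogeneous strategy (all
#'     concentrations to P, all five rate constants to Y).}
#'   \item{omm2}{heterogeneous strategy: the enzyme kinetic constants are
#'     forced independent (P), leaving the substrate concentration as the
#'     only independent concentration.}
#'   \item{omm3}{sublinear strategy: the zero-order synthesis rate constant
#'     is kept independent in P, which requires a pseudospecies.}
#'   \item{omm4}{superlinear variant: catalysis goes with the square of the
#'     complex; the squared concentration sits in Y via a pseudospecies.}
#'   \item{fum1}{fumarase with the four substrates frozen: a linear model,
#'     solvable by King-Altman; Y holds the five enzyme-form concentrations.}
#'   \item{fum2}{fumarase with time-varying substrates: Y holds the four
#'     substrate concentrations and the six unimolecular (dissociation) rate
#'     constants, P the five enzyme forms and the six association rate
#'     constants (|Y| = 10).}
#'   \item{toy_switch}{the positive-feedback switch of [toy_switch()], with
#'     its homogeneous partition and reference parameter values.}
#'   \item{xearm}{not bundled; see [load_xearm()].}
#' }
#'
#' @param name fixture name.
#' @return list with `name`, `model`, `phi`, and where relevant `frozen`
#'   (fum1) and `values` (toy_switch reference realization).
#' @export
fixture <- function(name = c("omm1", "omm2", "omm3", "omm4",
                             "fum1", "fum2", "toy_switch", "xearm")) {
  name <- match.arg(name)
  if (name == "xearm") {
    stop("supplementary required: the xEARM model is not bundled. ",
         "Transcribe the published supplementary file 'xearm.mpl' ",
         "(58 species, 115 reactions) into the reaction format and use ",
         "load_xearm(path).")
  }
  switch(name,
    omm1 = {
      m <- parse_model(OMM_DOC)
      list(name = name, model = m,
           phi = partition_map(m, Y = c("k1", "k2", "k3", "k4", "k5")))
    },
    omm2 = {
      m <- parse_model(OMM_DOC)
      list(name = name, model = m,
           phi = partition_map(m, Y = c("E", "ES", "P", "k4")))
    },
    omm3 = {
      m <- parse_model(OMM_DOC)
      list(name = name, model = m,
           phi = partition_map(m, Y = c("k1", "k2", "k3", "k5")))
    },
    omm4 = {
      m <- parse_model(OMM4_DOC)
      list(name = name, model = m,
           phi = partition_map(m, Y = c("k1", "k4", "k5", "ES")))
    },
    fum1 = {
      m <- parse_model(FUMARASE_DOC)
      list(name = name, model = m, frozen = FUM_SUBSTRATES,
           phi = partition_map(m, Y = FUM_ENZYMES, frozen = FUM_SUBSTRATES))
    },
    fum2 = {
      m <- parse_model(FUMARASE_DOC)
      list(name = name, model = m,
           phi = partition_map(m, Y = c(FUM_SUBSTRATES,
                                        paste0("d", 1:6))))
    },
    toy_switch = {
      m <- toy_switch()
      list(name = name, model = m,
           phi = partition_map(m, Y = c("ks", "kds", "k0", "kf", "kda", "kc")),
           values = c(S = 1, A = 1, kds = 0.01, kf = 0.2, kda = 1, kc = 0.02))
    })
}

#' Desk-scale positive-feedback switch model
#'
#' A two-species mass action module: a slowly turned-over signal `S` drives
#' autocatalytic production of `A` (velocity `kf*S*A^2`), balanced by basal
#' synthesis, first-order decay and a third-order sink that keeps the induced
#' state bounded. Under the reference realization the low state is the steady
#' state, and a step increase in `S` beyond a threshold fold-change tips `A`
#' onto the induced branch -- a bounded stand-in for switch-like dose
#' responses. Its threshold values are internal ground truth for the
#' perturbation tools, not measurements of any published system.
#'
#' @return a `mass_action_model`.
#' @export
toy_switch <- function() parse_model(TOY_SWITCH_DOC)

#' Generate a random first-order reaction model
#'
#' Draws `n_reactions` distinct directed first-order conversions between
#' `n_species` species, uniformly without replacement, and rejects draws
#' whose reaction graph is not weakly connected (disjoint networks are
#' discarded and redrawn). Reproducible under `seed`; the global RNG state is
#' left untouched.
#'
#' @param n_species number of species (named `S1 ...`).
#' @param n_reactions number of reactions (`>= n_species - 1`).
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap.
#' @return a `mass_action_model`.
#' @export
random_linear_model <- function(n_species, n_reactions, seed,
                                max_tries = 1000L) {
  if (n_reactions < n_species - 1L)
    stop("connectivity impossible: need at least n_species - 1 reactions")
  if (n_reactions > n_species * (n_species - 1L))
    stop("more reactions than distinct ordered species pairs")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  species <- paste0("S", seq_len(n_species))
  pairs <- expand.grid(from = seq_len(n_species), to = seq_len(n_species))
  pairs <- pairs[pairs$from != pairs$to, ]
  for (try in seq_len(max_tries)) {
    idx <- sample(nrow(pairs), n_reactions)
    g <- igraph::graph_from_data_frame(
      data.frame(from = species[pairs$from[idx]], to = species[pairs$to[idx]]),
      vertices = species, directed = TRUE)
    if (!igraph::is_connected(g, mode = "weak")) next
    lines <- paste0(species[pairs$from[idx]], " -> ", species[pairs$to[idx]],
                    " ; k", seq_len(n_reactions))
    doc <- paste(c(paste("species:", paste(species, collapse = " ")), lines),
                 collapse = "\n")
    return(parse_model(doc))
  }
  stop("failed to draw a weakly connected model in ", max_tries, " tries")
}

#' Load a user-transcribed xEARM model
#'
#' The extended extrinsic apoptosis reaction model (xEARM: EARM v1.0 plus
#' synthesis/degradation fluxes so a non-trivial steady state exists) is not
#' bundled; users transcribe the published supplementary description
#' (`xearm.mpl`) into the plain-text reaction format. This loader parses the
#' file and enforces the declared schema before returning it.
#'
#' @param path reaction-format file holding the transcription.
#' @return a validated `mass_action_model`.
#' @export
load_xearm <- function(path) {
  model <- read_model(path)
  validate_xearm(model)
  model
}

#' Validate a model against the xEARM schema
#'
#' Checks the declared shape of the xEARM transcription: 58 species and 115
#' reactions (after reversible expansion).
#'
#' @param model a `mass_action_model`.
#' @return the model, invisibly, if valid; otherwise an error.
#' @export
validate_xearm <- function(model) {
  stopifnot(inherits(model, "mass_action_model"))
  if (length(model$species) != 58L)
    stop("xEARM schema violation: expected 58 species, found ",
         length(model$species))
  if (length(model$reactions) != 115L)
    stop("xEARM schema violation: expected 115 reactions, found ",
         length(model$reactions))
  invisible(model)
}
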