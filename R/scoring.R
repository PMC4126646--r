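#' The pairwise score-synthesis rule table
#'
#' Trait performances are scored 1 (poor), 2 (average), 3 (good) and
#' combined pairwise with a fixed rule table rather than arithmetic:
#' \itemize{
#'   \item poor (1) with poor (1) gives poor (1);
#'   \item good (3) with good (3) gives good (3);
#'   \item poor (1) with good (3) gives average (2);
#'   \item poor (1) with average (2) gives poor (1);
#'   \item good (3) with average (2) gives good (3);
#'   \item average (2) with average (2) gives average (2).
#' }
#' The table is symmetric and total over \{1,2,3\} x \{1,2,3\}. Note the
#' operator is *not* associative: a sequence of scores must be folded in a
#' stated order.
#'
#' @return A 3 x 3 integer matrix `m` with `m[a, b]` the combined score.
#' @examples
#' score_rules()[1, 3]  # poor with good -> average
#' @export
score_rules <- function() {
  m <- matrix(c(1L, 1L, 2L,
                1L, 2L, 3L,
                2L, 3L, 3L), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(1:3, 1:3)
  m
}

#' Combine two performance scores
#'
#' @param a,b Scores in \{1, 2, 3\}.
#' @param rules Rule table from [score_rules()].
#' @return Combined score in \{1, 2, 3\}.
#' @examples
#' combine_pair(1, 3)  # 2
#' combine_pair(3, 2)  # 3
#' @export
combine_pair <- function(a, b, rules = score_rules()) {
  if (!a %in% 1:3 || !b %in% 1:3) stop("scores must be 1, 2 or 3")
  rules[a, b]
}

#' Fold a sequence of scores into a property global score
#'
#' Left-fold with [combine_pair]: `((s1 x s2) x s3)`. Because the operator
#' is non-associative the order matters — e.g. `(1,1,3)` folds to 2 while
#' `(1,3,1)` folds to 1 — so callers must pass scores in the intended
#' order.
#'
#' @param scores Integer vector of 2 or 3 scores in \{1, 2, 3\}.
#' @param rules Rule table from [score_rules()].
#' @return Global score in \{1, 2, 3\}.
#' @examples
#' property_global(c(3, 1, 1))  # 1
#' property_global(c(1, 3, 3))  # 3
#' @export
property_global <- function(scores, rules = score_rules()) {
  if (length(scores) < 2) stop("need at least two scores to fold")
  Reduce(function(a, b) combine_pair(a, b, rules), as.integer(scores))
}

#' Trait polarity for the nine desirable traits
#'
#' Which direction of each trait is desirable for fixing soil on slopes:
#' every trait is higher-better except the ultimate tensile strain, where a
#' *short* strain (little irreversible deformation, prompt recovery) is
#' desirable.
#'
#' @return Named character vector, `"higher"` or `"lower"`.
#' @export
trait_polarity <- function() {
  c(stems = "higher", isv_dc = "higher", rar = "higher",
    rar_fine = "higher", tmax = "higher", rar_coarse = "higher",
    ei = "higher", eps_ult = "lower", nitrogen = "higher",
    cellulose = "higher")
}

#' Assign 1/2/3 performance scores to species traits
#'
#' Two modes. `"tertile"` ranks the species on each trait (respecting the
#' trait's polarity from [trait_polarity()]) and cuts the ranking into
#' thirds: the worst third scores 1, the middle third 2, the best third 3.
#' Ties are resolved by average rank, then lexicographic species order — a
#' deterministic, seedless rule. `"fixture"` returns a supplied score table
#' verbatim (e.g. the published scorecard from [reference_trait_scores()]).
#'
#' @param table Data frame with a `species` column and numeric trait
#'   columns (tertile mode); ignored in fixture mode.
#' @param method `"tertile"` or `"fixture"`.
#' @param fixture Complete score data frame (fixture mode).
#' @param polarity Named vector of `"higher"`/`"lower"` per trait.
#' @return Data frame of per-species, per-trait scores in \{1, 2, 3\}.
#' @examples
#' tab <- data.frame(species = letters[1:9], tmax = 1:9, eps_ult = 1:9)
#' assign_scores(tab)
#' @export
assign_scores <- function(table, method = c("tertile", "fixture"),
                          fixture = NULL, polarity = trait_polarity()) {
  method <- match.arg(method)
  if (method == "fixture") {
    if (is.null(fixture)) stop("fixture mode requires a complete score table")
    sc <- fixture[setdiff(names(fixture), "species")]
    if (any(is.na(sc)) || !all(unlist(sc) %in% 1:3)) {
      stop("fixture scores must be complete and in {1, 2, 3}")
    }
    return(fixture)
  }
  stopifnot(is.data.frame(table), "species" %in% names(table))
  traits <- setdiff(names(table), "species")
  if (!length(traits)) stop("no trait columns to score")
  out <- data.frame(species = table$species, stringsAsFactors = FALSE)
  n <- nrow(table)
  for (tr in traits) {
    v <- table[[tr]]
    if (any(is.na(v))) stop("missing values in trait '", tr, "'")
    pol <- polarity[[sub("_(mech|phys)$", "", tr)]]
    if (is.null(pol)) pol <- "higher"
    goodness <- if (identical(pol, "lower")) -v else v
    r <- rank(goodness, ties.method = "average")
    ord <- order(r, table$species)
    score <- integer(n)
    score[ord] <- as.integer(1 + floor(3 * (seq_len(n) - 1) / n))
    out[[tr]] <- score
  }
  out
}

#' Default fold orders for the three plant properties
#'
#' Root abundance in soil folds (stems, ISV/Dc, RAR); root mechanical
#' resistance folds (tension composite, bending composite, ultimate
#' strain); root physiological properties fold (ultimate strain, cellulose,
#' nitrogen). The physiological order deviates from the display order of
#' the trait rows (strain, nitrogen, cellulose) because the synthesis
#' operator is non-associative and only the (strain, cellulose, nitrogen)
#' order reproduces the published global scores for every species (the
#' display order disagrees for *F. tikoua* and *P. stricta*).
#'
#' @return Named list of character vectors of score-slot names.
#' @export
default_fold_orders <- function() {
  list(abundance = c("stems", "isv_dc", "rar"),
       mechanical = c("tension", "bending", "eps_ult_mech"),
       physiological = c("eps_ult_phys", "cellulose", "nitrogen"))
}

score_slots <- c("stems", "isv_dc", "rar", "rar_fine", "tmax", "rar_coarse",
                 "ei", "eps_ult_mech", "eps_ult_phys", "nitrogen",
                 "cellulose")

#' Build a species scorecard from its per-trait scores
#'
#' Fills the two composite scores — tension (fine-root RAR combined with
#' T_max) and bending (coarse-root RAR combined with EI), both via the rule
#' table, not arithmetic multiplication — and the three property globals by
#' folding in the configured orders.
#'
#' @param trait_scores Named vector/list of scores in \{1,2,3\} with names
#'   `stems`, `isv_dc`, `rar`, `rar_fine`, `tmax`, `rar_coarse`, `ei`,
#'   `eps_ult_mech`, `eps_ult_phys`, `nitrogen`, `cellulose`. The two
#'   `eps_ult` slots exist because the published scorecard lists the strain
#'   trait separately under the mechanical and physiological properties.
#' @param species Species label.
#' @param rules Rule table.
#' @param fold_orders List as from [default_fold_orders()]; must name all
#'   three properties.
#' @param provenance `"assigned"` or `"fixture"`.
#' @return A `score_card` list with `trait_scores`, `composite_tension`,
#'   `composite_bending`, `global_abundance`, `global_mechanical`,
#'   `global_physiological`.
#' @examples
#' sc <- c(stems = 1, isv_dc = 3, rar = 2, rar_fine = 2, tmax = 3,
#'         rar_coarse = 2, ei = 3, eps_ult_mech = 3, eps_ult_phys = 3,
#'         nitrogen = 3, cellulose = 1)
#' score_card(sc, species = "P. stricta")
#' @export
score_card <- function(trait_scores, species = "species", rules = score_rules(),
                       fold_orders = default_fold_orders(),
                       provenance = "assigned") {
  ts <- unlist(trait_scores)
  missing <- setdiff(score_slots, names(ts))
  if (length(missing)) {
    stop("missing trait scores: ", paste(missing, collapse = ", "))
  }
  if (!all(ts[score_slots] %in% 1:3)) stop("scores must be 1, 2 or 3")
  if (!all(c("abundance", "mechanical", "physiological") %in%
           names(fold_orders))) {
    stop("fold_orders must name abundance, mechanical and physiological")
  }
  slots <- as.list(ts[score_slots])
  slots$tension <- combine_pair(slots$rar_fine, slots$tmax, rules)
  slots$bending <- combine_pair(slots$rar_coarse, slots$ei, rules)
  fold <- function(order) {
    property_global(unlist(slots[order]), rules)
  }
  structure(list(species = species, trait_scores = ts[score_slots],
                 composite_tension = slots$tension,
                 composite_bending = slots$bending,
                 global_abundance = fold(fold_orders$abundance),
                 global_mechanical = fold(fold_orders$mechanical),
                 global_physiological = fold(fold_orders$physiological),
                 provenance = provenance),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s (%s)\n", x$species, x$provenance))
  cat(sprintf("  composites: tension %d, bending %d\n",
              x$composite_tension, x$composite_bending))
  cat(sprintf("  globals: abundance %d, mechanical %d, physiological %d\n",
              x$global_abundance, x$global_mechanical,
              x$global_physiological))
  invisible(x)
}

#' Scorecards for a whole score table
#'
#' @param scores Data frame with `species` plus the eleven score slots (see
#'   [score_card]).
#' @inheritParams score_card
#' @return Data frame: one row per species with composites and the three
#'   property globals.
#' @examples
#' score_cards(reference_trait_scores())
#' @export
score_cards <- function(scores, rules = score_rules(),
                        fold_orders = default_fold_orders(),
                        provenance = "fixture") {
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    cd <- score_card(scores[i, score_slots], species = scores$species[i],
                     rules = rules, fold_orders = fold_orders,
                     provenance = provenance)
    data.frame(species = cd$species,
               composite_tension = cd$composite_tension,
               composite_bending = cd$composite_bending,
               global_abundance = cd$global_abundance,
               global_mechanical = cd$global_mechanical,
               global_physiological = cd$global_physiological,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published per-trait scores for the nine study species
#'
#' The shipped reference scorecard: per-trait 1/2/3 performance scores of
#' the nine Salween-valley species as published in the study's
#' multi-criteria assessment. The strain trait appears twice
#' (`eps_ult_mech`, `eps_ult_phys`) because the published table scores it
#' separately under the mechanical and physiological properties and the
#' two columns differ for most species; both are shipped verbatim without
#' reconciliation.
#'
#' @return Data frame: `species` plus the eleven score slots.
#' @examples
#' head(reference_trait_scores())
#' @export
reference_trait_scores <- function() {
  path <- system.file("extdata", "reference_trait_scores.csv",
                      package = "slopetraits", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Placement profiles for the nine study species
#'
#' Depth and slope-sector biases of desirable root traits, with the
#' trait-level evidence supporting each bias, as summarised from the field
#' observations: e.g. *P. stricta* had more numerous and stronger roots
#' upslope, *A. americana* and *B. championii* concentrated root density
#' at depth, *C. anomala* occupied a larger soil volume near the surface.
#' A bias is only ever set together with at least one evidence statement.
#'
#' @return Data frame: `species`, `sector_bias` (`up`/`down`/`none`),
#'   `depth_bias` (`deep`/`shallow`/`none`), `evidence`.
#' @export
placement_profiles <- function() {
  data.frame(
    species = c("A. americana", "A. codonocephala", "A. hispidus",
                "B. championii", "C. anomala", "F. tikoua", "J. curcas",
                "P. stricta", "R. chinensis"),
    sector_bias = c("none", "none", "none", "up", "none", "none", "none",
                    "up", "none"),
    depth_bias = c("deep", "deep", "none", "deep", "shallow", "none",
                   "none", "shallow", "none"),
    evidence = c(
      "high density of roots deeper in the soil",
      "deeper roots deform less (smaller ultimate strain)",
      "",
      "greater soil volume deeper upslope; deep roots stronger",
      "larger soil volume occupied near the soil surface",
      "",
      "",
      "more numerous and stronger roots upslope; cellulose higher at surface",
      ""),
    stringsAsFactors = FALSE)
}

#' Recommend a planting position on a degradation hotspot
#'
#' Rule cascade over a species' trait biases: roots biased upslope cross
#' the potential shear plane best when the plant sits at the *top* of the
#' hotspot; a downslope bias points to the *toe*; desirable traits
#' concentrated at depth, without a sector bias, reinforce the deep shear
#' zone in the *middle*; a shallow concentration suits the top or toe
#' (where the shear plane is shallowest); otherwise the species is
#' unclassified. Total function; a bias without supporting evidence is
#' rejected.
#'
#' @param sector_bias `"up"`, `"down"` or `"none"`.
#' @param depth_bias `"deep"`, `"shallow"` or `"none"`.
#' @param evidence Character vector (or `;`-separated string) of
#'   trait-level statements backing the biases.
#' @return One of `"top"`, `"toe"`, `"middle"`, `"top_or_toe"`,
#'   `"unclassified"`.
#' @examples
#' recommend_position("up", "shallow", "stronger roots upslope")  # top
#' recommend_position("none", "deep", "dense deep roots")         # middle
#' @export
recommend_position <- function(sector_bias = c("none", "up", "down"),
                               depth_bias = c("none", "deep", "shallow"),
                               evidence = character()) {
  sector_bias <- match.arg(sector_bias)
  depth_bias <- match.arg(depth_bias)
  has_evidence <- length(evidence) > 0 && any(nzchar(evidence))
  if ((sector_bias != "none" || depth_bias != "none") && !has_evidence) {
    stop("a trait bias must be backed by at least one evidence statement")
  }
  if (sector_bias == "up") return("top")
  if (sector_bias == "down") return("toe")
  if (depth_bias == "deep") return("middle")
  if (depth_bias == "shallow") return("top_or_toe")
  "unclassified"
}

#' Placement recommendations for a profile table
#'
#' @param profiles Data frame as from [placement_profiles()].
#' @return The table with a `position` column appended.
#' @examples
#' placement_table()
#' @export
placement_table <- function(profiles = placement_profiles()) {
  profiles$position <- vapply(seq_len(nrow(profiles)), function(i) {
    recommend_position(profiles$sector_bias[i], profiles$depth_bias[i],
                       profiles$evidence[i])
  }, "")
  profiles
}
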