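# Derived sample phenotypes and screen calls: high/low-proliferation classes
# from Ki67 staining and mitotic index, lysate-microarray (LMA) z-scores and
# hit calling, and the concordance of a screen effect with the tumor
# differential-expression direction.

#' Proliferation class from Ki67 and mitotic-index categories
#'
#' HP (highly proliferative) iff the pair is (high, high), (high, moderate)
#' or (moderate, high); LP (weakly proliferative) iff (negative, low),
#' (negative, moderate) or (moderate, low); every other combination --
#' including any missing category -- is unassigned.
#'
#' @param ki67 Character vector: \code{"negative"}, \code{"moderate"},
#'   \code{"high"} or \code{"missing"}.
#' @param mi Character vector: \code{"low"}, \code{"moderate"}, \code{"high"}
#'   or \code{"missing"}.
#' @return Character vector: \code{"HP"}, \code{"LP"} or
#'   \code{"unassigned"}.
#' @examples
#' proliferation_class("high", "high")     # HP
#' proliferation_class("negative", "low")  # LP
#' proliferation_class("high", "low")      # unassigned
#' @export
proliferation_class <- function(ki67, mi) {
  hp <- (ki67 == "high" & mi %in% c("high", "moderate")) |
        (ki67 == "moderate" & mi == "high")
  lp <- (ki67 == "negative" & mi %in% c("low", "moderate")) |
        (ki67 == "moderate" & mi == "low")
  ifelse(hp, "HP", ifelse(lp, "LP", "unassigned"))
}

#' LMA z-scores against negative controls
#'
#' z = (signal - mean(controls)) / sd(controls), per readout.
#'
#' @param signals Numeric vector of per-miRNA readouts.
#' @param negative_controls Numeric vector of at least two negative-control
#'   replicate readouts with nonzero spread.
#' @return Numeric vector of z-scores aligned with \code{signals}.
#' @export
lma_zscores <- function(signals, negative_controls) {
  if (length(negative_controls) < 2L)
    stop("need at least 2 negative-control replicates")
  s <- stats::sd(negative_controls)
  if (!is.finite(s) || s == 0) stop("negative controls have zero spread")
  (signals - mean(negative_controls)) / s
}

#' Call screen hits from 48 h and 72 h z-scores
#'
#' A miRNA has an effect iff at least one |z| exceeds 2, both |z| exceed 1,
#' and the two time points agree in sign; the effect direction is the shared
#' sign.
#'
#' @param z48,z72 Numeric z-scores at 48 h and 72 h (vectorized).
#' @return A data.frame with columns \code{z48}, \code{z72}, \code{hit}
#'   (logical) and \code{effect_direction} (\code{"increase"},
#'   \code{"decrease"} or \code{"none"}).
#' @examples
#' lma_hit_call(2.5, 1.2)   # hit, increase
#' lma_hit_call(2.5, 0.5)   # no hit
#' @export
lma_hit_call <- function(z48, z72) {
  hit <- pmax(abs(z48), abs(z72)) > 2 & pmin(abs(z48), abs(z72)) > 1 &
    sign(z48) == sign(z72)
  dir <- ifelse(hit, ifelse(z48 > 0, "increase", "decrease"), "none")
  data.frame(z48 = z48, z72 = z72, hit = hit, effect_direction = dir,
             stringsAsFactors = FALSE)
}

#' Concordance of a screen effect with the tumor DE direction
#'
#' \code{"matching"} iff a miRNA up-regulated in highly proliferative tumors
#' increases Ki67 in the screen (or down-regulated and decreases);
#' \code{"opposite"} for a hit with the reverse pairing; \code{"none"} when
#' the screen called no hit.
#'
#' @param tumor_direction \code{"up_in_HP"} or \code{"down_in_HP"}
#'   (vectorized).
#' @param hit Logical screen hit flag (vectorized), e.g. from
#'   \code{\link{lma_hit_call}}.
#' @param effect_direction \code{"increase"}, \code{"decrease"} or
#'   \code{"none"} (vectorized).
#' @return Character vector: \code{"matching"}, \code{"opposite"} or
#'   \code{"none"}.
#' @export
concordance_with_tumor_de <- function(tumor_direction, hit, effect_direction) {
  stopifnot(all(tumor_direction %in% c("up_in_HP", "down_in_HP")))
  match_dir <- ifelse(tumor_direction == "up_in_HP", "increase", "decrease")
  ifelse(!hit | effect_direction == "none", "none",
         ifelse(effect_direction == match_dir, "matching", "opposite"))
}
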