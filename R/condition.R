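#' Digestion-condition parameters
#'
#' Bundles everything that distinguishes one simulated sample from another:
#' the survival of short NDR footprints, the per-nucleosome-index downstream
#' redistribution of rotational occupancy, its coupling to gene-length
#' quartile, whether the 5'-most (+1/+2) nucleosomes participate in the
#' shift, the mixture weights over protection classes, the MNase dose, and
#' the linker:nucleosomal cleavage-rate ratio.
#'
#' `shift_magnitude_bp[k]` is the signed number of base pairs of rotational
#' occupancy redistributed one 10-bp step downstream at nucleosome index k;
#' a magnitude of m corresponds to moving a fraction m/10 of the occupancy
#' mass (before gene-length coupling).
#'
#' @param ndr_protection_scale fraction in [0,1]; survival probability of
#'   short NDR footprints under high MNase dose.
#' @param shift_magnitude_bp numeric vector of length 10 (indices +1..+10),
#'   signed bp of occupancy redistribution per index.
#' @param shift_length_coupling multiplier per gene-length quartile
#'   (named Q1..Q4, shortest to longest).
#' @param five_prime_shift_enabled if FALSE, indices +1 and +2 never shift
#'   regardless of their magnitude entry.
#' @param class_weights mixture weights over the five protection classes
#'   `nucleosome`, `hexasome`, `tetrasome`, `ndr_short`, `background`;
#'   must sum to 1.
#' @param mnase_dose `"high"` (heavy digestion) or `"low"` (gentle digestion).
#' @param linker_rate_ratio per-bp cleavage rate in linker DNA relative to
#'   nucleosome-protected DNA (> 1; default 25).
#' @param rotational_weights unnormalized occupancy weights of the seven
#'   rotational offsets -30,-20,...,+30 bp, decaying away from the dyad.
#' @return An object of class `condition_params`.
#' @seealso [mutant_presets()] for the wild-type and Spn1-mutant presets.
#' @export
condition_params <- function(ndr_protection_scale = 1,
                             shift_magnitude_bp = numeric(10),
                             shift_length_coupling = c(Q1 = 0.4, Q2 = 0.8,
                                                       Q3 = 1.2, Q4 = 1.6),
                             five_prime_shift_enabled = FALSE,
                             class_weights = c(nucleosome = 0.55,
                                               hexasome = 0.15,
                                               tetrasome = 0.08,
                                               ndr_short = 0.07,
                                               background = 0.15),
                             mnase_dose = c("high", "low"),
                             linker_rate_ratio = 25,
                             rotational_weights = c(0.04, 0.12, 0.30, 1,
                                                    0.30, 0.12, 0.04)) {
  mnase_dose <- match.arg(mnase_dose)
  if (length(shift_magnitude_bp) != 10L)
    stop("`shift_magnitude_bp` must have one entry per nucleosome index +1..+10")
  cls <- c("nucleosome", "hexasome", "tetrasome", "ndr_short", "background")
  if (!setequal(names(class_weights), cls))
    stop("`class_weights` must be named: ", paste(cls, collapse = ", "))
  class_weights <- class_weights[cls]
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("`class_weights` must sum to 1")
  if (any(class_weights < 0)) stop("`class_weights` must be non-negative")
  if (ndr_protection_scale < 0 || ndr_protection_scale > 1)
    stop("`ndr_protection_scale` must lie in [0, 1]")
  if (linker_rate_ratio <= 1) stop("`linker_rate_ratio` must exceed 1")
  if (length(rotational_weights) != 7L || any(rotational_weights < 0))
    stop("`rotational_weights` must be 7 non-negative weights")
  if (!setequal(names(shift_length_coupling), paste0("Q", 1:4)))
    stop("`shift_length_coupling` must be named Q1..Q4")

  structure(list(
    ndr_protection_scale = ndr_protection_scale,
    shift_magnitude_bp = stats::setNames(as.numeric(shift_magnitude_bp),
                                         paste0("+", 1:10)),
    shift_length_coupling = shift_length_coupling[paste0("Q", 1:4)],
    five_prime_shift_enabled = isTRUE(five_prime_shift_enabled),
    class_weights = class_weights,
    mnase_dose = mnase_dose,
    linker_rate_ratio = linker_rate_ratio,
    rotational_weights = rotational_weights
  ), class = "condition_params")
}

#' Wild-type and Spn1-mutant digestion presets
#'
#' Returns the parameter set emulating one of the three strains:
#' \describe{
#'   \item{WT}{full NDR protection, no positioning shift.}
#'   \item{K192N}{NDR short-footprint protection collapses under high MNase
#'     dose (but survives gentle digestion); gene-body nucleosomes from index
#'     +3 onward redistribute occupancy one rotational step downstream, with
#'     magnitude growing with nucleosome index and gene length; +1/+2 are
#'     never shifted.}
#'   \item{141-305}{NDR intact; the downstream redistribution is stronger and
#'     extends to the +1 and +2 nucleosomes.}
#' }
#'
#' @param name one of `"WT"`, `"K192N"`, `"141-305"`.
#' @param ... overrides passed on to [condition_params()].
#' @return A `condition_params` object.
#' @examples
#' mutant_presets("K192N")$ndr_protection_scale
#' @export
mutant_presets <- function(name, ...) {
  if (length(name) != 1L || !name %in% c("WT", "K192N", "141-305"))
    stop("unknown preset: ", paste(name, collapse = ", "),
         " (expected \"WT\", \"K192N\" or \"141-305\")")
  args <- switch(name,
    "WT" = list(),
    "K192N" = list(
      ndr_protection_scale = 0.1,
      shift_magnitude_bp = c(0, 0, pmin(4, 1.0 + 0.3 * (3:10 - 3))),
      five_prime_shift_enabled = FALSE
    ),
    "141-305" = list(
      ndr_protection_scale = 1,
      shift_magnitude_bp = pmin(5, 1.5 + 0.3 * (1:10 - 1)),
      five_prime_shift_enabled = TRUE
    )
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(condition_params, args)
}

#' @export
print.condition_params <- function(x, ...) {
  cat("MNase digestion condition\n")
  cat(sprintf("  dose: %s   linker:nucleosomal rate ratio: %g\n",
              x$mnase_dose, x$linker_rate_ratio))
  cat(sprintf("  NDR protection scale: %g\n", x$ndr_protection_scale))
  shifted <- which(x$shift_magnitude_bp != 0)
  if (length(shifted)) {
    cat(sprintf("  shifted indices: %s (5' shift %s)\n",
                paste0("+", shifted, collapse = ","),
                if (x$five_prime_shift_enabled) "enabled" else "disabled"))
  } else cat("  no positioning shift\n")
  cat("  class weights: ",
      paste(sprintf("%s=%.2f", names(x$class_weights), x$class_weights),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read digestion-condition parameters from a YAML file
#'
#' The YAML file may contain any subset of the arguments of
#' [condition_params()], or a single key `preset` naming one of the
#' [mutant_presets()] (other keys then act as overrides).
#'
#' @param path path to a YAML file.
#' @return A `condition_params` object.
#' @export
read_condition_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    preset <- cfg$preset
    cfg$preset <- NULL
    return(do.call(mutant_presets, c(list(name = preset), lapply(cfg, unlist))))
  }
  do.call(condition_params, lapply(cfg, unlist))
}
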