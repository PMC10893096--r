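#' Convert a nutrient mass to a millimolar concentration
#'
#' Grams are divided by the molecular weight to obtain mol, divided by the
#' reference volume to obtain mol/L, and multiplied by 1000 to obtain
#' mmol/L (mM). The reference volume makes the implied grams-to-
#' concentration conversion explicit; at the default 1 L the arithmetic is
#' exactly grams / MW * 1000.
#'
#' @param grams nutrient mass, g (per day); vectorized.
#' @param molecular_weight g/mol; vectorized.
#' @param volume reference volume, L.
#' @return concentration in mM.
#' @export
grams_to_millimolar <- function(grams, molecular_weight, volume = 1.0) {
  if (any(molecular_weight <= 0)) stop("molecular weight must be positive")
  if (any(volume <= 0)) stop("volume must be positive")
  if (any(grams < 0)) stop("grams must be non-negative")
  grams / molecular_weight / volume * 1000
}

#' Convert a participant's diet to metabolite concentrations
#'
#' Nutrients are translated to exchange metabolites via the nutrient map and
#' converted with [grams_to_millimolar()]; nutrients sharing a metabolite
#' are summed. Unmapped nutrients are skipped with a message (or raise in
#' strict mode) and recorded in the `"unmapped"` attribute.
#'
#' @param diet data.frame with columns `nutrient` and `grams`.
#' @param map data.frame with columns `nutrient`, `metabolite`, `mol_weight`.
#' @param volume reference volume (L) for the conversion.
#' @param strict error on nutrients missing from the map.
#' @return named numeric vector, metabolite -> mM (a diet constraint set).
#' @export
diet_to_constraints <- function(diet, map, volume = 1.0, strict = FALSE) {
  stopifnot(all(c("nutrient", "grams") %in% names(diet)),
            all(c("nutrient", "metabolite", "mol_weight") %in% names(map)))
  if (anyDuplicated(map$nutrient)) stop("nutrient map has duplicated nutrients")
  if (any(map$mol_weight <= 0)) stop("molecular weight must be positive")
  unknown <- setdiff(diet$nutrient, map$nutrient)
  if (length(unknown) > 0) {
    if (strict) stop("unmapped nutrient(s): ", paste(unknown, collapse = ", "))
    message("skipping ", length(unknown), " unmapped nutrient(s): ",
            paste(unknown, collapse = ", "))
  }
  keep <- diet[diet$nutrient %in% map$nutrient, , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- setNames(numeric(0), character(0))
  } else {
    i <- match(keep$nutrient, map$nutrient)
    mm <- grams_to_millimolar(keep$grams, map$mol_weight[i], volume)
    out <- tapply(mm, map$metabolite[i], sum)
    out <- setNames(as.numeric(out), names(out))
  }
  attr(out, "unmapped") <- unknown
  out
}

#' Blend a personal diet with a reference diet
#'
#' Per-metabolite convex combination over the union of metabolites, with
#' absent entries treated as 0. The default 99% personal / 1% reference
#' blend supplements each personal diet with a trace of a Western-style
#' reference so model-specific growth requirements are met.
#'
#' @param personal,reference named numeric vectors (metabolite -> mM).
#' @param w_personal weight of the personal diet, in \[0, 1\].
#' @return named numeric vector over the union of metabolites.
#' @export
blend_diets <- function(personal, reference, w_personal = 0.99) {
  if (w_personal < 0 || w_personal > 1) stop("w_personal must be in [0, 1]")
  mets <- union(names(personal), names(reference))
  p <- setNames(rep(0, length(mets)), mets)
  p[names(personal)] <- personal
  r <- setNames(rep(0, length(mets)), mets)
  r[names(reference)] <- reference
  w_personal * p + (1 - w_personal) * r
}

#' Reference Western-style diet (synthetic)
#'
#' A small editable metabolite -> mM table shipped with the package
#' (`inst/extdata/western_diet_synthetic.csv`). It is a synthetic stand-in
#' with the composition shape of a Western reference diet, not a copy of
#' any curated resource.
#'
#' @param path optional CSV (columns `metabolite`, `mM`) overriding the
#'   shipped table.
#' @return named numeric vector, metabolite -> mM.
#' @export
western_diet <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "western_diet_synthetic.csv",
                        package = "commfba", mustWork = TRUE)
  }
  x <- read.csv(path)
  setNames(x$mM, x$metabolite)
}

#' Read per-participant diet CSV files
#'
#' @param path CSV with columns `nutrient`, `grams` and optionally
#'   `participant`.
#' @return a named list of data.frames, one per participant (a single
#'   unnamed-participant file yields a list of length one).
#' @export
read_diet_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("nutrient", "grams") %in% names(x)))
  if (any(x$grams < 0)) stop("negative gram intake in '", path, "'")
  if (is.null(x$participant)) x$participant <- "participant1"
  split(x[, c("nutrient", "grams")], x$participant)
}

#' Read a nutrient -> exchange-metabolite map
#'
#' @param path CSV with columns `nutrient`, `metabolite`, `mol_weight`.
#' @return the validated data.frame.
#' @export
read_nutrient_map <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("nutrient", "metabolite", "mol_weight") %in% names(x)))
  if (any(x$mol_weight <= 0)) stop("molecular weight must be positive")
  x
}
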