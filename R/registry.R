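#' Taxonomy registry of the order Myxococcales
#'
#' The 30 currently described genera of the order *Myxococcales*, each with
#' its family and suborder.  The order splits into three suborders
#' (*Cystobacterineae*, *Sorangiineae*, *Nannocystineae*) and 11 families.
#' This registry is the fixed label universe for every dataset handled by
#' the package: genus labels are validated against it and suborder labels
#' are derived from it.
#'
#' @return A data.frame with columns `genus`, `family` and `suborder`
#'   (30 rows, one per genus), ordered alphabetically by genus.
#' @examples
#' reg <- genus_registry()
#' table(reg$suborder)
#' @export
genus_registry <- function() {
  reg <- rbind(
    # Cystobacterineae
    c("Archangium",       "Cystobacteraceae",      "Cystobacterineae"),
    c("Cystobacter",      "Cystobacteraceae",      "Cystobacterineae"),
    c("Hyalangium",       "Cystobacteraceae",      "Cystobacterineae"),
    c("Melittangium",     "Cystobacteraceae",      "Cystobacterineae"),
    c("Stigmatella",      "Cystobacteraceae",      "Cystobacterineae"),
    c("Vitiosangium",     "Cystobacteraceae",      "Cystobacterineae"),
    c("Corallococcus",    "Myxococcaceae",         "Cystobacterineae"),
    c("Myxococcus",       "Myxococcaceae",         "Cystobacterineae"),
    c("Pyxidicoccus",     "Myxococcaceae",         "Cystobacterineae"),
    c("Aggregicoccus",    "Myxococcaceae",         "Cystobacterineae"),
    c("Angiococcus",      "Myxococcaceae",         "Cystobacterineae"),
    c("Anaeromyxobacter", "Anaeromyxobacteraceae", "Cystobacterineae"),
    c("Vulgatibacter",    "Vulgatibacteraceae",    "Cystobacterineae"),
    # Sorangiineae
    c("Byssovora",        "Polyangiaceae",         "Sorangiineae"),
    c("Chondromyces",     "Polyangiaceae",         "Sorangiineae"),
    c("Jahnella",         "Polyangiaceae",         "Sorangiineae"),
    c("Polyangium",       "Polyangiaceae",         "Sorangiineae"),
    c("Sorangium",        "Polyangiaceae",         "Sorangiineae"),
    c("Aetherobacter",    "Polyangiaceae",         "Sorangiineae"),
    c("Minicystis",       "Polyangiaceae",         "Sorangiineae"),
    c("Racemicystis",     "Polyangiaceae",         "Sorangiineae"),
    c("Sandaracinus",     "Sandaracinaceae",       "Sorangiineae"),
    c("Phaselicystis",    "Phaselicystidaceae",    "Sorangiineae"),
    c("Labilithrix",      "Labilitrichaceae",      "Sorangiineae"),
    # Nannocystineae
    c("Enhygromyxa",      "Nannocystaceae",        "Nannocystineae"),
    c("Nannocystis",      "Nannocystaceae",        "Nannocystineae"),
    c("Plesiocystis",     "Nannocystaceae",        "Nannocystineae"),
    c("Pseudenhygromyxa", "Nannocystaceae",        "Nannocystineae"),
    c("Kofleria",         "Kofleriaceae",          "Nannocystineae"),
    c("Haliangium",       "Haliangiaceae",         "Nannocystineae")
  )
  reg <- data.frame(genus = reg[, 1], family = reg[, 2], suborder = reg[, 3],
                    stringsAsFactors = FALSE)
  reg[order(reg$genus), , drop = FALSE]
}

#' Suborder names of the order Myxococcales
#' @return Character vector of the three suborder names.
#' @export
myxo_suborders <- function() {
  c("Cystobacterineae", "Sorangiineae", "Nannocystineae")
}

#' Look up the suborder of one or more genera
#'
#' @param genus character vector of genus names.
#' @return Character vector of suborders, same length as `genus`.
#' @export
genus_to_suborder <- function(genus) {
  reg <- genus_registry()
  i <- match(genus, reg$genus)
  if (anyNA(i)) {
    stop("unknown genus: ", paste(unique(genus[is.na(i)]), collapse = ", "))
  }
  reg$suborder[i]
}

#' Published per-genus image counts of the MYXO.DB collection
#'
#' The number of single fruiting-body images available per genus in the
#' reference collection (322 images over the 30 genera).  Used by the
#' synthetic generator to emulate the collection's class-size imbalance and
#' by the subset-filtering examples (removing classes with fewer than 4
#' samples leaves 25 classes / 313 images; fewer than 8 leaves 22 classes).
#'
#' @return Named integer vector (names are genera, sum is 322).
#' @export
myxodb_class_sizes <- function() {
  n <- c(
    Aggregicoccus = 11L, Anaeromyxobacter = 1L, Archangium = 8L,
    Cystobacter = 10L, Hyalangium = 9L, Melittangium = 9L,
    Stigmatella = 14L, Corallococcus = 15L, Myxococcus = 38L,
    Pyxidicoccus = 13L, Haliangium = 5L, Kofleria = 10L,
    Enhygromyxa = 1L, Nannocystis = 14L, Plesiocystis = 8L,
    Pseudenhygromyxa = 4L, Phaselicystis = 13L, Byssovora = 3L,
    Chondromyces = 17L, Jahnella = 11L, Polyangium = 9L,
    Sorangium = 21L, Sandaracinus = 14L, Minicystis = 20L,
    Vulgatibacter = 1L, Aetherobacter = 14L, Angiococcus = 9L,
    Racemicystis = 11L, Vitiosangium = 6L, Labilithrix = 3L
  )
  n[order(names(n))]
}
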