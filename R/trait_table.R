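#' @name trait_levels
#' @title Category sets for the tip trait table
#' @description Cusp-number categories are ordinal (`"1" < "2" < "3" <
#'   "4plus"`; teeth with four or more cusps form one category). Diet
#'   categories follow the plant-consumption gradient `carnivore <
#'   insectivore < omnivore < herbivore`.
#' @export
cusp_levels <- c("1", "2", "3", "4plus")

#' @rdname trait_levels
#' @export
diet_levels <- c("carnivore", "insectivore", "omnivore", "herbivore")

#' Load and validate a tip trait table
#'
#' Reads a CSV (or accepts a data frame) with columns `species`, `cusp`,
#' `diet`. Cusp values may be given as numbers (4 and above collapse to
#' `"4plus"`) or as the category labels themselves. Every category must come
#' from the closed sets [cusp_levels] / [diet_levels]; duplicates and unknown
#' values are errors naming the offending row.
#'
#' @param x path to a CSV file, or a data frame.
#' @param tree optional `phylo`; mismatches between table and tree tips are
#'   reported in the `mismatch` attribute.
#' @return a `trait_table` data frame with factor columns `cusp` (ordered)
#'   and `diet` (ordered), and attribute `mismatch` when a tree was given.
#' @export
load_traits <- function(x, tree = NULL) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else
    as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("species", "cusp", "diet")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trait table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$species <- as.character(df$species)
  dup <- df$species[duplicated(df$species)]
  if (length(dup)) stopf("duplicate species in trait table: %s",
                         paste(unique(dup), collapse = ", "))
  cusp <- as.character(df$cusp)
  suppressWarnings(num <- as.numeric(cusp))
  cusp[!is.na(num) & num >= 4] <- "4plus"
  bad <- which(!cusp %in% cusp_levels)
  if (length(bad)) stopf("unknown cusp category %s in row %d (species %s)",
                         cusp[bad[1]], bad[1], df$species[bad[1]])
  diet <- as.character(df$diet)
  bad <- which(!diet %in% diet_levels)
  if (length(bad)) stopf("unknown diet category %s in row %d (species %s)",
                         diet[bad[1]], bad[1], df$species[bad[1]])
  out <- data.frame(species = df$species,
                    cusp = factor(cusp, levels = cusp_levels, ordered = TRUE),
                    diet = factor(diet, levels = diet_levels, ordered = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  if (!is.null(tree)) {
    mm <- list(absent_from_tree = setdiff(out$species, tree$tip.label),
               absent_from_table = setdiff(tree$tip.label, out$species))
    attr(out, "mismatch") <- mm
  }
  out
}

## The five binarisation schemes. 1 is always the derived pole
## (more complex teeth / more plant consumption).
binarize_schemes <- list(
  cusp_1_v_2plus    = function(tt) as.integer(tt$cusp != "1"),
  cusp_12_v_3plus   = function(tt) as.integer(tt$cusp %in% c("3", "4plus")),
  cusp_123_v_4plus  = function(tt) as.integer(tt$cusp == "4plus"),
  diet_pred_v_plant = function(tt) as.integer(tt$diet %in% c("omnivore", "herbivore")),
  diet_herb_v_rest  = function(tt) as.integer(tt$diet == "herbivore")
)

#' Binarise a trait table under a named scheme
#'
#' Recodes the four-level cusp or diet character to 0/1 under one of the five
#' cut points used for the correlated-evolution tests. State 1 is always the
#' derived pole (multicuspid / plant-consuming).
#'
#' @param table a `trait_table` from [load_traits()].
#' @param scheme one of `"cusp_1_v_2plus"`, `"cusp_12_v_3plus"`,
#'   `"cusp_123_v_4plus"`, `"diet_pred_v_plant"`, `"diet_herb_v_rest"`.
#' @return data frame `species`, `state` (0/1 integer), with attribute
#'   `scheme`; a warning is emitted when the recoded column is constant.
#' @examples
#' tt <- load_traits(data.frame(species = c("A", "B"),
#'                              cusp = c(1, 3),
#'                              diet = c("carnivore", "herbivore")))
#' binarize(tt, "cusp_1_v_2plus")
#' @export
binarize <- function(table, scheme) {
  if (!scheme %in% names(binarize_schemes))
    stopf("unknown binarisation scheme '%s' (choose from: %s)", scheme,
          paste(names(binarize_schemes), collapse = ", "))
  st <- binarize_schemes[[scheme]](table)
  if (length(unique(st)) < 2L)
    warnf("scheme '%s' yields a constant trait column", scheme)
  out <- data.frame(species = table$species, state = st,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  out
}

#' Named tip-state vector for one trait column
#'
#' Extracts a trait column as a named character vector aligned to the
#' tree's tip labels — the form the likelihood and reconstruction
#' functions consume. Errors if any tip lacks a record.
#'
#' @param table a `trait_table`.
#' @param tree a `phylo`.
#' @param trait `"cusp"` or `"diet"`.
#' @export
tip_state_vector <- function(table, tree, trait = c("cusp", "diet")) {
  trait <- match.arg(trait)
  miss <- setdiff(tree$tip.label, table$species)
  if (length(miss)) stopf("tip(s) missing from trait table: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  v <- as.character(table[[trait]])
  names(v) <- table$species
  v[tree$tip.label]
}
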