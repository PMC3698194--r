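trait_schema <- c("species", "tree_name", "family", "diet", "manipulation",
                  "body_mass_g", "thorax_mass_g", "fmr", "wing_area_cm2",
                  "wing_loading_g_cm2", "head_width_mm", "source")
trait_numeric <- c("manipulation", "body_mass_g", "thorax_mass_g", "fmr",
                   "wing_area_cm2", "wing_loading_g_cm2", "head_width_mm")

#' Read a species trait table
#'
#' Reads a CSV in the standard trait-table schema (columns `species`,
#' `tree_name`, `family`, `diet`, `manipulation`, `body_mass_g`,
#' `thorax_mass_g`, `fmr`, `wing_area_cm2`, `wing_loading_g_cm2`,
#' `head_width_mm`, `source`; empty cells are missing values, never zero)
#' and validates it with [validate_traits()].
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                 na.strings = c("", "NA"))
  validate_traits(df)
  df
}

#' Validate a species trait table
#'
#' Hard schema violations (missing columns, non-numeric measurement cells,
#' manipulation codes outside \{0, 1\}, non-positive masses or areas,
#' duplicate `tree_name`) raise an error naming the offending rows.
#' Internal inconsistencies that may be legitimate data features (thorax
#' at least as heavy as the body, stated `fmr`/`wing_loading_g_cm2`
#' disagreeing with values derived from the raw columns by more than 1%
#' relative) are returned as flags, not errors.
#'
#' @param traits data.frame or CSV path.
#' @return (invisibly) a data.frame of flagged inconsistencies with
#'   columns `row`, `species`, `issue`.
#' @export
validate_traits <- function(traits) {
  df <- if (is.character(traits)) {
    read.csv(traits, stringsAsFactors = FALSE, strip.white = TRUE,
             na.strings = c("", "NA"))
  } else traits
  miss <- setdiff(trait_schema, names(df))
  if (length(miss))
    stop("trait table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in trait_numeric) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad))
        stop("non-numeric values in '", col, "' at row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      df[[col]] <- as.numeric(v)
    }
  }
  bad <- which(!is.na(df$manipulation) & !df$manipulation %in% c(0, 1))
  if (length(bad))
    stop("manipulation must be 0 (UtM) or 1 (AtM); offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (col in c("body_mass_g", "thorax_mass_g", "wing_area_cm2",
                "wing_loading_g_cm2", "fmr")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop("'", col, "' must be positive; offending row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(df$tree_name) & !is.na(df$tree_name))
  if (length(dup))
    stop("duplicate tree_name at row(s): ", paste(dup, collapse = ", "),
         call. = FALSE)

  flags <- data.frame(row = integer(), species = character(),
                      issue = character(), stringsAsFactors = FALSE)
  flag <- function(rows, what) {
    if (length(rows))
      flags <<- rbind(flags, data.frame(row = rows,
                                        species = df$species[rows],
                                        issue = what,
                                        stringsAsFactors = FALSE))
  }
  flag(which(!is.na(df$thorax_mass_g) & !is.na(df$body_mass_g) &
               df$thorax_mass_g >= df$body_mass_g),
       "thorax mass >= body mass")
  both <- which(!is.na(df$fmr) & !is.na(df$thorax_mass_g) &
                  !is.na(df$body_mass_g) &
                  df$thorax_mass_g < df$body_mass_g)
  if (length(both)) {
    derived <- 0.95 * df$thorax_mass_g[both] / df$body_mass_g[both]
    flag(both[abs(derived - df$fmr[both]) / df$fmr[both] > 0.01],
         "stated fmr disagrees with 0.95 * thorax/body by > 1%")
  }
  both <- which(!is.na(df$wing_loading_g_cm2) & !is.na(df$wing_area_cm2) &
                  !is.na(df$body_mass_g))
  if (length(both)) {
    derived <- df$body_mass_g[both] / df$wing_area_cm2[both]
    flag(both[abs(derived - df$wing_loading_g_cm2[both]) /
                df$wing_loading_g_cm2[both] > 0.01],
         "stated wing loading disagrees with body mass / wing area by > 1%")
  }
  invisible(flags)
}

#' Derive FMR and wing loading from raw measurements where absent
#'
#' Fills the `fmr` column from `0.95 * thorax_mass_g / body_mass_g` and
#' `wing_loading_g_cm2` from `body_mass_g / wing_area_cm2` for rows where
#' the derived quantity is missing but its raw inputs are present.  Stated
#' values are never overwritten.
#'
#' @param traits a validated trait data.frame.
#' @return the data.frame with derived columns filled in.
#' @export
derive_traits <- function(traits) {
  i <- which(is.na(traits$fmr) & !is.na(traits$thorax_mass_g) &
               !is.na(traits$body_mass_g) &
               traits$thorax_mass_g < traits$body_mass_g)
  if (length(i))
    traits$fmr[i] <- fmr(traits$thorax_mass_g[i], traits$body_mass_g[i])
  i <- which(is.na(traits$wing_loading_g_cm2) & !is.na(traits$wing_area_cm2) &
               !is.na(traits$body_mass_g))
  if (length(i))
    traits$wing_loading_g_cm2[i] <-
      wing_loading(traits$body_mass_g[i], traits$wing_area_cm2[i])
  traits
}

#' Bundled 28-species trait table
#'
#' Wet body mass, flight muscle ratio, wing loading, diet and food-load
#' manipulation ability for 28 bee and wasp species (10 bees, 18 wasps;
#' 14 able and 14 unable to manipulate their food load), as used in the
#' package's worked analyses.  `tree_name` gives the taxon used in the
#' phylogenetic reconstruction for each morphospecies and links rows to
#' the tips of [hymeflight_tree()].
#'
#' @return a data.frame in the standard trait-table schema.
#' @export
hymeflight_table1 <- function() {
  read_traits(system.file("extdata", "table1.csv", package = "hymeflight",
                          mustWork = TRUE))
}

#' Bundled reference phylogeny
#'
#' A rooted 28-tip tree for the species of [hymeflight_table1()]:
#' Vespidae sister to the Apoidea, Sphecidae basal to the remaining
#' apoids, Crabronidae monophyletic, Apidae and Megachilidae monophyletic
#' sisters, congeners grouped, solitary vespids basal to the social ones.
#' Because posterior branch lengths for the underlying consensus topology
#' are not available, branch lengths are assigned by Grafen's method
#' ([grafen_lengths()]); the tree is ultrametric with depth 1 and is an
#' approximation, swappable for any user-supplied Newick file.
#'
#' @return a `"phylo"` object with 28 tips.
#' @export
hymeflight_tree <- function() {
  read_phylogeny(system.file("extdata", "tree_fig1.nwk",
                             package = "hymeflight", mustWork = TRUE))
}
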