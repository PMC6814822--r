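#' Closed category vocabularies for social system and diet
#'
#' Social systems follow the four-category scheme used in comparative work
#' on carnivoran social organisation; diets follow the five-category
#' scheme based on the percentage of terrestrial vertebrates, arthropods,
#' plant material, or aquatic prey in the diet.
#'
#' @format character vectors.
#' @name regime_vocabularies
NULL

#' @rdname regime_vocabularies
#' @export
SOCIAL_SYSTEMS <- c("territorial_solitary", "pair_living", "group_living",
                    "variable")

#' @rdname regime_vocabularies
#' @export
DIET_CATEGORIES <- c("carnivory", "omnivory", "insectivory", "herbivory",
                     "aquatic_carnivory")

#' @rdname regime_vocabularies
#' @export
COMBINED_REGIMES <- c("group_carnivory", "group_omnivory", "group_other",
                      "solitary_carnivory", "solitary_omnivory",
                      "solitary_other")

#' Size dimorphism index (SDI)
#'
#' `SDI = +-((S_L / S_S) - 1) * 100`, where `S_L` and `S_S` are the mean
#' body masses of the larger and smaller sex. The sign is positive when
#' the male is the larger sex and negative when the female is; equal
#' masses give exactly 0. The index is reported in percent: SDI = 50 means
#' the larger sex is 1.5 times the mass of the smaller.
#'
#' @param male_mass,female_mass mean body masses (g), strictly positive.
#'   Vectorized; recycled to common length.
#' @return signed SDI in percent.
#' @examples
#' compute_sdi(1500, 1000)  # +50: males 50% heavier
#' compute_sdi(800, 1000)   # -25: females larger
#' @export
compute_sdi <- function(male_mass, female_mass) {
  if (any(!is.finite(male_mass)) || any(!is.finite(female_mass)) ||
      any(male_mass <= 0) || any(female_mass <= 0))
    stop("masses must be finite and strictly positive")
  sl <- pmax(male_mass, female_mass)
  ss <- pmin(male_mass, female_mass)
  sign(male_mass - female_mass) * (sl / ss - 1) * 100
}

#' Combined social x diet selective regime
#'
#' Collapses the four social systems to solitary/group (territorial
#' solitary stays solitary; pair-living, group-living and variable groups
#' aggregate to group) and the five diets to carnivory/omnivory/other
#' (insectivory, herbivory and aquatic carnivory aggregate to other), and
#' returns the six-level cross-product label.
#'
#' @param social social system, one of [SOCIAL_SYSTEMS]. Vectorized.
#' @param diet diet category, one of [DIET_CATEGORIES]. Vectorized.
#' @return combined regime, one of [COMBINED_REGIMES].
#' @examples
#' assign_combined_regime("territorial_solitary", "carnivory")
#' @export
assign_combined_regime <- function(social, diet) {
  bad_s <- setdiff(unique(social), SOCIAL_SYSTEMS)
  if (length(bad_s) > 0L)
    stop("unknown social system(s): ", paste(bad_s, collapse = ", "),
         "; allowed: ", paste(SOCIAL_SYSTEMS, collapse = ", "))
  bad_d <- setdiff(unique(diet), DIET_CATEGORIES)
  if (length(bad_d) > 0L)
    stop("unknown diet(s): ", paste(bad_d, collapse = ", "),
         "; allowed: ", paste(DIET_CATEGORIES, collapse = ", "))
  soc2 <- ifelse(social == "territorial_solitary", "solitary", "group")
  diet2 <- ifelse(diet %in% c("carnivory", "omnivory"), diet, "other")
  paste(soc2, diet2, sep = "_")
}

#' Collapse social system / diet to their aggregated forms
#'
#' @param social social system values.
#' @return `"solitary"` or `"group"`.
#' @export
collapse_social <- function(social) {
  bad <- setdiff(unique(social), SOCIAL_SYSTEMS)
  if (length(bad) > 0L) stop("unknown social system(s): ",
                             paste(bad, collapse = ", "))
  ifelse(social == "territorial_solitary", "solitary", "group")
}

#' @rdname collapse_social
#' @param diet diet values.
#' @export
collapse_diet <- function(diet) {
  bad <- setdiff(unique(diet), DIET_CATEGORIES)
  if (length(bad) > 0L) stop("unknown diet(s): ", paste(bad, collapse = ", "))
  ifelse(diet %in% c("carnivory", "omnivory"), diet, "other")
}

#' Load and validate a species trait table
#'
#' Reads a CSV/TSV with columns `species`, `male_mass_g`, `female_mass_g`,
#' `social_system`, `diet` (delimiter sniffed from the extension: `.tsv` /
#' `.txt` means tab, otherwise comma), validates every row, and derives
#' `sdi_percent` and `combined_regime`. Row-level problems (non-positive
#' or unparseable masses, unknown categories) are collected and reported
#' together; duplicated species are an error. Categories are taken as
#' given and never reclassified -- species-level judgement calls (e.g.
#' classifying lions as territorial solitary because males defend the
#' pride's territory) belong in the data, not in the loader.
#'
#' @param file path to the table, or a `data.frame` with the same columns.
#' @return a `trait_table`: a data.frame with the five input columns plus
#'   `sdi_percent` and `combined_regime`.
#' @export
load_trait_table <- function(file) {
  df <- if (is.data.frame(file)) {
    file
  } else {
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
    read.csv(file, sep = sep, stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
  }
  required <- c("species", "male_mass_g", "female_mass_g", "social_system",
                "diet")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df$species <- normalize_label(as.character(df$species))
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup) > 0L)
    stop("duplicated species: ", paste(dup, collapse = ", "))

  problems <- character()
  for (col in c("male_mass_g", "female_mass_g")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v) | v <= 0)
    if (length(bad) > 0L)
      problems <- c(problems, sprintf("row %d (%s): %s '%s' is not a positive mass",
                                      bad, df$species[bad], col, df[[col]][bad]))
    df[[col]] <- v
  }
  bad_s <- which(!(df$social_system %in% SOCIAL_SYSTEMS))
  if (length(bad_s) > 0L)
    problems <- c(problems, sprintf("row %d (%s): unknown social_system '%s'",
                                    bad_s, df$species[bad_s],
                                    df$social_system[bad_s]))
  bad_d <- which(!(df$diet %in% DIET_CATEGORIES))
  if (length(bad_d) > 0L)
    problems <- c(problems, sprintf("row %d (%s): unknown diet '%s'",
                                    bad_d, df$species[bad_d], df$diet[bad_d]))
  if (length(problems) > 0L)
    stop("invalid trait table rows:\n  ", paste(problems, collapse = "\n  "))

  df$sdi_percent <- compute_sdi(df$male_mass_g, df$female_mass_g)
  df$combined_regime <- assign_combined_regime(df$social_system, df$diet)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write the derived analysis table
#'
#' Writes the trait table (including the derived `sdi_percent` and
#' `combined_regime` columns) back to CSV.
#'
#' @param table a `trait_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trait_table <- function(table, file) {
  write.csv(as.data.frame(table), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
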