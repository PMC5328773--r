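#' Sex-by-genotype category labels
#'
#' The six "gender categories" of a het-by-het cross: each pup is classified by
#' sex (m/f) and *Kcnma1* genotype (WT, het, KO). Under Mendelian segregation
#' the categories occur with fractions 1/8, 1/8, 1/4, 1/4, 1/8, 1/8; collapsing
#' over sex leaves the familiar 1/4 : 1/2 : 1/4 genotype ratio.
#'
#' @param scheme `"six"` for the sex-by-genotype categories or `"three"` for
#'   genotypes with sexes combined.
#' @return `gender_categories()` returns the category labels in canonical
#'   order; `category_fractions()` returns the named vector of Mendelian
#'   fractions for the chosen scheme (always summing to 1).
#' @examples
#' category_fractions("six")
#' category_fractions("three")
#' @export
gender_categories <- function(scheme = c("six", "three")) {
  scheme <- match.arg(scheme)
  if (scheme == "six") c("mWT", "fWT", "mhet", "fhet", "mKO", "fKO")
  else c("WT", "het", "KO")
}

#' @rdname gender_categories
#' @export
category_fractions <- function(scheme = c("six", "three")) {
  scheme <- match.arg(scheme)
  if (scheme == "six") {
    stats::setNames(c(1, 1, 2, 2, 1, 1) / 8, gender_categories("six"))
  } else {
    stats::setNames(c(1, 2, 1) / 4, gender_categories("three"))
  }
}

genotype_levels <- function() c("WT", "het", "KO")

#' Classify pups into sex-by-genotype categories
#'
#' @param sex character vector of `"M"`/`"F"`.
#' @param genotype character vector of `"WT"`/`"het"`/`"KO"` (NA allowed).
#' @return character vector of category labels (`NA` where genotype is
#'   unknown).
#' @export
pup_category <- function(sex, genotype) {
  ifelse(is.na(genotype), NA_character_,
         paste0(ifelse(sex == "M", "m", "f"), genotype))
}

# ---- record validation ------------------------------------------------------

pup_columns <- c("pup_id", "litter_id", "sex", "genotype", "death_day", "weaned")
litter_columns <- c("litter_id", "dam_id", "parity", "birth_date", "period",
                    "complete")

fail_rows <- function(what, rows, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  stop(sprintf("%s%s (row %s)", what, where,
               paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
}

#' Validate colony pup and litter records
#'
#' Checks the schema and referential integrity of a colony record set:
#' required columns, legal sex/genotype/period codes, nonnegative integer
#' death days, the weaning consistency rule (a weaned pup cannot have died at
#' or before postnatal day 21), the rule that genotype may be unknown only for
#' pups that died, and that every `litter_id` in the pup table resolves to
#' exactly one litter. Malformed rows are reported by row number.
#'
#' @param pups data frame of pup records (`pup_id`, `litter_id`, `sex`,
#'   `genotype`, `death_day`, `weaned`).
#' @param litters data frame of litter records (`litter_id`, `dam_id`,
#'   `parity`, `birth_date`, `period`, `complete`).
#' @return invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_colony <- function(pups, litters) {
  miss <- setdiff(pup_columns, names(pups))
  if (length(miss))
    stop("pup table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(litter_columns, names(litters))
  if (length(miss))
    stop("litter table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  bad <- which(!pups$sex %in% c("M", "F"))
  if (length(bad)) fail_rows("unknown sex code", bad, "pups")
  bad <- which(!is.na(pups$genotype) & !pups$genotype %in% genotype_levels())
  if (length(bad)) fail_rows("unknown genotype code", bad, "pups")
  dd <- pups$death_day
  bad <- which(!is.na(dd) & (dd < 0 | dd != round(dd)))
  if (length(bad)) fail_rows("death_day must be a nonnegative integer", bad, "pups")
  bad <- which(pups$weaned & !is.na(dd) & dd <= 21)
  if (length(bad)) fail_rows("weaned pup with death_day <= 21", bad, "pups")
  # genotype may be unknown only for pups that died (dated or undated deaths)
  bad <- which(is.na(pups$genotype) & pups$weaned)
  if (length(bad)) fail_rows("genotype unknown for a weaned pup", bad, "pups")

  if (anyDuplicated(litters$litter_id))
    fail_rows("duplicate litter_id", which(duplicated(litters$litter_id)), "litters")
  bad <- which(!pups$litter_id %in% litters$litter_id)
  if (length(bad)) fail_rows("dangling litter_id", bad, "pups")
  bad <- which(!litters$period %in% c("construction", "quiescent"))
  if (length(bad)) fail_rows("unknown period flag", bad, "litters")
  bad <- which(!is.na(litters$parity) & litters$parity < 1)
  if (length(bad)) fail_rows("parity must be >= 1", bad, "litters")
  invisible(TRUE)
}

# ---- CSV readers / writers --------------------------------------------------

read_csv_checked <- function(file, required) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(basename(file), " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x
}

#' Read and write colony record CSVs
#'
#' A colony directory holds one comma-separated, UTF-8, headered file per
#' record type: `litters.csv` and `pups.csv` (and optionally `weights.csv`,
#' `composition.csv`, `glucose.csv`, read by their own readers). Dates are
#' ISO-8601. Readers validate records on load; writers emit a deterministic
#' column order so a write/read round trip is the identity on records.
#'
#' @param dir directory containing (or to receive) the CSV files.
#' @param colony list with elements `litters` and `pups`.
#' @return `read_colony()` returns `list(litters, pups)` with validated,
#'   type-converted columns; `write_colony()` returns the directory path,
#'   invisibly.
#' @export
read_colony <- function(dir) {
  litters <- read_csv_checked(file.path(dir, "litters.csv"), litter_columns)
  pups <- read_csv_checked(file.path(dir, "pups.csv"), pup_columns)
  litters$birth_date <- as.Date(litters$birth_date)
  litters$parity <- as.integer(litters$parity)
  litters$complete <- as.logical(litters$complete)
  pups$death_day <- as.integer(pups$death_day)
  pups$weaned <- as.logical(pups$weaned)
  pups$genotype[!is.na(pups$genotype) & pups$genotype == ""] <- NA_character_
  validate_colony(pups, litters)
  list(litters = litters, pups = pups)
}

#' @rdname read_colony
#' @export
write_colony <- function(colony, dir) {
  validate_colony(colony$pups, colony$litters)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  litters <- colony$litters[, litter_columns]
  litters$birth_date <- format(as.Date(litters$birth_date), "%Y-%m-%d")
  utils::write.csv(litters, file.path(dir, "litters.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(colony$pups[, pup_columns], file.path(dir, "pups.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(dir)
}

#' Read weekly weights, QMR composition, or glucose timecourse CSVs
#'
#' `weights.csv` is long format (`mouse_id`, `category`, `age_week`,
#' `weight_g`); `composition.csv` holds one QMR measurement per row
#' (`mouse_id`, `category`, `total_weight_g`, `lean_g`, `fat_g`,
#' `total_water_g`, `free_water_g`); `glucose.csv` holds timed samples
#' (`mouse_id`, `test`, `minutes`, `mmol_l`). Basic invariants (positive
#' weights, free water not exceeding total water, strictly increasing times
#' starting at 0) are enforced on read.
#'
#' @param file path to the CSV file.
#' @return a validated data frame.
#' @export
read_weights <- function(file) {
  x <- read_csv_checked(file, c("mouse_id", "category", "age_week", "weight_g"))
  bad <- which(x$weight_g <= 0 | x$age_week < 3)
  if (length(bad)) fail_rows("weights must be > 0 g at age_week >= 3", bad, file)
  if (anyDuplicated(x[, c("mouse_id", "age_week")]))
    stop("duplicate (mouse_id, age_week) in ", basename(file), call. = FALSE)
  x[order(x$mouse_id, x$age_week), ]
}

#' @rdname read_weights
#' @export
read_composition <- function(file) {
  x <- read_csv_checked(file, c("mouse_id", "category", "total_weight_g",
                                "lean_g", "fat_g", "total_water_g",
                                "free_water_g"))
  bad <- which(x$free_water_g > x$total_water_g)
  if (length(bad)) fail_rows("free water exceeds total water", bad, file)
  bad <- which(x$lean_g + x$fat_g + x$free_water_g > 1.05 * x$total_weight_g)
  if (length(bad)) fail_rows("component sum exceeds 105% of total weight", bad, file)
  x
}

#' @rdname read_weights
#' @export
read_glucose <- function(file) {
  x <- read_csv_checked(file, c("mouse_id", "test", "minutes", "mmol_l"))
  bad <- which(!x$test %in% c("ipGTT", "ipITT"))
  if (length(bad)) fail_rows("test must be ipGTT or ipITT", bad, file)
  for (id in unique(x$mouse_id)) {
    for (tt in unique(x$test[x$mouse_id == id])) {
      s <- x[x$mouse_id == id & x$test == tt, ]
      if (any(diff(s$minutes) <= 0) || s$minutes[1] != 0)
        stop("glucose samples for ", id, "/", tt,
             " must start at 0 min and strictly increase", call. = FALSE)
    }
  }
  x
}

# ---- category tallies -------------------------------------------------------

#' Tally pups into Mendelian categories
#'
#' Counts pups over the six sex-by-genotype categories (or the three collapsed
#' genotypes). Pups with unknown genotype cannot be categorized; they are
#' excluded from the tally and the exclusion count is attached as the
#' `"excluded"` attribute (and raised as a message when nonzero).
#'
#' @param pups pup record data frame.
#' @param scheme `"six"` or `"three"`.
#' @param filter optional logical vector over rows of `pups` (e.g.
#'   `pups$weaned`) selecting which pups to count.
#' @return named integer vector of counts in canonical category order; sums to
#'   the number of genotyped pups passing the filter.
#' @examples
#' pups <- data.frame(sex = c("M", "F", "M"), genotype = c("WT", "KO", "het"))
#' tally_categories(pups)
#' @export
tally_categories <- function(pups, scheme = c("six", "three"), filter = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(filter)) pups <- pups[filter, , drop = FALSE]
  if (nrow(pups) == 0) {
    warning("empty pup selection; returning all-zero counts")
    return(stats::setNames(integer(length(gender_categories(scheme))),
                           gender_categories(scheme)))
  }
  excluded <- sum(is.na(pups$genotype))
  pups <- pups[!is.na(pups$genotype), , drop = FALSE]
  key <- if (scheme == "six") pup_category(pups$sex, pups$genotype)
         else pups$genotype
  counts <- table(factor(key, levels = gender_categories(scheme)))
  out <- stats::setNames(as.integer(counts), gender_categories(scheme))
  attr(out, "excluded") <- excluded
  if (excluded > 0)
    message(excluded, " pup(s) with unknown genotype excluded from tally")
  out
}
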