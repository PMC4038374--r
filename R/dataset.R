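#' @keywords internal
"_PACKAGE"

## Canonical column layout of a trait table CSV and the trait identifiers
## used throughout the package.  Units are fixed: masses in grams,
## hindlimb length in centimetres; intercepts therefore carry these units.
.trait_csv_columns <- c(
  "species", "clade", "n",
  "body_mass_g", "hindlimb_length_cm", "thigh_mass_g", "shank_mass_g",
  "pes_mass_g", "tars_mass_g", "digit_mass_g"
)

.trait_names <- c(
  body_mass = "body_mass_g",
  hindlimb_length = "hindlimb_length_cm",
  thigh_mass = "thigh_mass_g",
  shank_mass = "shank_mass_g",
  pes_mass = "pes_mass_g",
  tars_mass = "tars_mass_g",
  digit_mass = "digit_mass_g"
)

#' Canonical trait identifiers
#'
#' The seven traits a trait table carries: body mass (g), hindlimb length
#' (cm), and the five hindlimb segment masses (g).
#'
#' @return Character vector of trait identifiers.
#' @export
trait_names <- function() names(.trait_names)

.missing_markers <- c("", "NA", "--")

#' Read a species-by-trait table
#'
#' Reads a CSV of species-mean morphometrics: one row per species with a
#' clade label, the number of specimens averaged, body mass (g), hindlimb
#' length (cm), and the five hindlimb segment masses (g).  Missing values
#' may be encoded as an empty field, `NA`, or `--`; they are retained as
#' missing (no imputation).  All present masses and lengths must be
#' strictly positive.
#'
#' Where a species has tarsometatarsal, digit, and pes masses all present,
#' their internal consistency (tars + digits ~ pes) is checked softly: a
#' deviation beyond 10 percent raises a warning naming the species, since
#' published tables round each entry independently.
#'
#' @param source Path to a CSV file, or a connection.
#' @param provenance Free-text description of where the table came from.
#' @return A `trait_table`: a data frame with columns `species`, `clade`,
#'   `n_specimens`, and the seven traits (canonical names, see
#'   [trait_names()]), plus attributes `provenance` and `clades` (the
#'   declared clade vocabulary, in order of first appearance).
#' @export
read_trait_table <- function(source, provenance = as.character(source)[1]) {
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L)
    stop("trait table is empty: no data rows found", call. = FALSE)
  if (!identical(sort(names(raw)), sort(.trait_csv_columns))) {
    unknown <- setdiff(names(raw), .trait_csv_columns)
    absent <- setdiff(.trait_csv_columns, names(raw))
    stop("trait table schema mismatch",
         if (length(unknown)) paste0("; unknown column(s): ",
                                     paste(unknown, collapse = ", ")),
         if (length(absent)) paste0("; missing column(s): ",
                                    paste(absent, collapse = ", ")),
         call. = FALSE)
  }

  parse_num <- function(col, positive = TRUE, integer = FALSE) {
    v <- raw[[col]]
    v[v %in% .missing_markers] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d (%s)",
                   v[bad[1]], col, bad[1], raw$species[bad[1]]),
           call. = FALSE)
    neg <- which(!is.na(out) & out <= 0)
    if (positive && length(neg))
      stop(sprintf("non-positive value %s in column '%s', row %d (%s)",
                   out[neg[1]], col, neg[1], raw$species[neg[1]]),
           call. = FALSE)
    if (integer && any(out[!is.na(out)] != round(out[!is.na(out)])))
      stop(sprintf("column '%s' must hold integers", col), call. = FALSE)
    out
  }

  species <- raw$species
  dup <- species[duplicated(species)]
  if (length(dup))
    stop("duplicate species name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)

  tab <- data.frame(
    species = species,
    clade = raw$clade,
    n_specimens = parse_num("n", integer = TRUE),
    stringsAsFactors = FALSE
  )
  for (tr in names(.trait_names))
    tab[[tr]] <- parse_num(.trait_names[[tr]])

  ## soft additivity check: pes = tars + digits up to rounding
  full <- !is.na(tab$tars_mass) & !is.na(tab$digit_mass) & !is.na(tab$pes_mass)
  if (any(full)) {
    rel <- abs(tab$tars_mass[full] + tab$digit_mass[full] - tab$pes_mass[full]) /
      tab$pes_mass[full]
    off <- which(rel > 0.10)
    if (length(off))
      warning("tars + digit mass deviates from pes mass by more than 10% for: ",
              paste(tab$species[full][off], collapse = ", "), call. = FALSE)
  }

  attr(tab, "provenance") <- provenance
  attr(tab, "clades") <- unique(tab$clade)
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d species, %d clade(s)\n", nrow(x),
              length(attr(x, "clades"))))
  cat("Provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Bundled neognath hindlimb segment-mass table
#'
#' Species means for 38 neognath bird species: body mass (g), passively
#' flexed hindlimb length (cm), and the masses (g) of the thigh, shank,
#' pes, tarsometatarsal segment, and digits, with clade labels
#' (24 species belong to the Land Birds subclade).  Two species lack
#' tarsometatarsal/digit masses and three lack hindlimb length; these are
#' genuine missing measurements.
#'
#' @return A `trait_table` with 38 rows.
#' @export
fixture_neognath <- function() {
  path <- system.file("extdata", "neognath_hindlimb_masses.csv",
                      package = "allomorph", mustWork = TRUE)
  read_trait_table(path, provenance = "bundled neognath hindlimb data")
}

.check_trait_name <- function(name) {
  if (!name %in% names(.trait_names))
    stop(sprintf("unknown trait '%s'; expected one of: %s", name,
                 paste(names(.trait_names), collapse = ", ")), call. = FALSE)
  name
}

#' Matched complete-case pair of log10-transformed traits
#'
#' Drops species missing either trait, log10-transforms the remainder, and
#' returns the matched vectors.  This is the unit of input for all the
#' regression machinery: species means on a log10 scale.
#'
#' @param table A `trait_table`.
#' @param x_name,y_name Canonical trait identifiers (see [trait_names()]).
#' @return A `variable_pair`: list with `x`, `y` (log10 values), `n`,
#'   `species`, `x_name`, `y_name`.
#' @export
pair_complete <- function(table, x_name, y_name) {
  stopifnot(inherits(table, "trait_table"))
  .check_trait_name(x_name); .check_trait_name(y_name)
  xr <- table[[x_name]]; yr <- table[[y_name]]
  keep <- !is.na(xr) & !is.na(yr)
  n <- sum(keep)
  if (n < 3L)
    stop(sprintf("insufficient data: only %d species have both %s and %s",
                 n, x_name, y_name), call. = FALSE)
  structure(
    list(x = log10(xr[keep]), y = log10(yr[keep]), n = n,
         species = table$species[keep], x_name = x_name, y_name = y_name),
    class = "variable_pair")
}

#' @export
print.variable_pair <- function(x, ...) {
  cat(sprintf("Variable pair: log10(%s) ~ log10(%s), n = %d species\n",
              x$y_name, x$x_name, x$n))
  invisible(x)
}

#' Restrict a trait table to one clade
#'
#' @param table A `trait_table`.
#' @param clade A clade label present in the table's declared vocabulary.
#' @return A `trait_table` with only that clade's rows, order preserved.
#' @export
subset_clade <- function(table, clade) {
  stopifnot(inherits(table, "trait_table"))
  known <- attr(table, "clades")
  if (!clade %in% known)
    stop(sprintf("unknown clade '%s'; known clades: %s", clade,
                 paste(known, collapse = ", ")), call. = FALSE)
  out <- table[table$clade == clade, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- paste0(attr(table, "provenance"),
                                    " [clade: ", clade, "]")
  attr(out, "clades") <- known
  class(out) <- c("trait_table", "data.frame")
  out
}
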