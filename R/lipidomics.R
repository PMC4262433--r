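#' Parse a TAG species label
#'
#' TAG species are named by the total number of acyl carbons and the total
#' number of double bonds over the three chains (`"54:3"`), or in
#' chain-resolved form (`"17:0/17:0/17:0"`). An optional `"TAG"` prefix and
#' either the ASCII colon or the typographic ratio character (U+2236) are
#' accepted; canonical output always uses ASCII.
#'
#' @param label a single species label.
#' @return an object of class `tag_species_key`: a list with
#'   `total_carbons`, `total_double_bonds`, `chains` (a 3 x 2 matrix of
#'   carbons/double bonds for the chain-resolved form, else `NULL`) and the
#'   canonical ASCII `label`.
#' @examples
#' parse_species_label("54:3")
#' parse_species_label("TAG17:0/17:0/17:0")
#' @export
parse_species_label <- function(label) {
  if (length(label) != 1L || !is.character(label) || is.na(label))
    stop("expected a single character label")
  x <- gsub("∶", ":", trimws(label))
  x <- sub("^TAG[ ]?", "", x)
  if (grepl("^[0-9]+:[0-9]+$", x)) {
    parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    key <- list(total_carbons = parts[1], total_double_bonds = parts[2],
                chains = NULL, label = x)
  } else if (grepl("^[0-9]+:[0-9]+/[0-9]+:[0-9]+/[0-9]+:[0-9]+$", x)) {
    chains <- do.call(rbind, lapply(strsplit(x, "/", fixed = TRUE)[[1]],
                                    function(ch) {
                                      as.integer(strsplit(ch, ":", fixed = TRUE)[[1]])
                                    }))
    colnames(chains) <- c("carbons", "double_bonds")
    key <- list(total_carbons = sum(chains[, "carbons"]),
                total_double_bonds = sum(chains[, "double_bonds"]),
                chains = chains, label = x)
  } else {
    stop("malformed TAG species label: '", label, "'")
  }
  if (key$total_carbons <= 0)
    stop("malformed TAG species label: '", label, "' (zero carbons)")
  class(key) <- "tag_species_key"
  key
}

#' @export
print.tag_species_key <- function(x, ...) {
  cat("TAG ", x$label, " (", x$total_carbons, " carbons, ",
      x$total_double_bonds, " double bonds",
      if (!is.null(x$chains)) ", chain-resolved", ")\n", sep = "")
  invisible(x)
}

check_lipidome <- function(table) {
  req <- c("species_label", "intensity", "is_standard")
  if (!all(req %in% names(table)))
    stop("lipidome table must have columns ",
         paste(req, collapse = ", "))
  invisible(table)
}

#' Normalize species intensities to the internal standard
#'
#' Divides every raw intensity by the raw intensity of the single spiked
#' internal standard row, the standard quantification scheme for shotgun
#' lipidomics with one spiked species (here TAG 17:0/17:0/17:0). Species
#' rows with zero intensity (undetected) are dropped first. Re-applying the
#' normalization is a no-op since it always recomputes from the raw column.
#'
#' @param table lipidome data frame with columns `species_label`,
#'   `intensity`, `is_standard`.
#' @return the table with a `normalized_intensity` column; the standard row
#'   normalizes to 1.
#' @export
normalize_to_standard <- function(table) {
  check_lipidome(table)
  table <- table[table$is_standard | table$intensity > 0, , drop = FALSE]
  std <- which(table$is_standard)
  if (length(std) != 1L)
    stop("exactly one internal-standard row required, found ", length(std))
  denom <- table$intensity[std]
  if (denom <= 0) stop("internal standard has non-positive intensity")
  table$normalized_intensity <- table$intensity / denom
  rownames(table) <- NULL
  table
}

#' Aggregate species into carbon:double-bond classes
#'
#' Sums standard-normalized intensities of all acyl isomers sharing the same
#' total carbon and double-bond count, the class level at which dominant TAG
#' species are reported. The internal standard is excluded. Normalization is
#' applied first if the table does not carry it yet.
#'
#' @inheritParams normalize_to_standard
#' @return data frame with columns `class`, `total_carbons`,
#'   `total_double_bonds`, `normalized_intensity`, sorted by intensity,
#'   descending.
#' @export
aggregate_by_class <- function(table) {
  check_lipidome(table)
  if (nrow(table) == 0L || all(table$is_standard)) {
    return(data.frame(class = character(), total_carbons = integer(),
                      total_double_bonds = integer(),
                      normalized_intensity = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!"normalized_intensity" %in% names(table))
    table <- normalize_to_standard(table)
  sp <- table[!table$is_standard, , drop = FALSE]
  keys <- lapply(sp$species_label, parse_species_label)
  cls <- vapply(keys, function(k)
    sprintf("%d:%d", k$total_carbons, k$total_double_bonds), character(1))
  agg <- rowsum(sp$normalized_intensity, cls)
  out <- data.frame(class = rownames(agg),
                    normalized_intensity = agg[, 1],
                    stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(out$class, ":", fixed = TRUE))
  out$total_carbons <- as.integer(parts[, 1])
  out$total_double_bonds <- as.integer(parts[, 2])
  out <- out[order(-out$normalized_intensity),
             c("class", "total_carbons", "total_double_bonds",
               "normalized_intensity")]
  rownames(out) <- NULL
  out
}

#' Compare class intensities between feeding conditions
#'
#' Aggregates both tables by class and reports the fed/unfed ratio of summed
#' normalized intensities. Classes detected in only one condition are kept
#' with an `NA` ratio rather than a fabricated value.
#'
#' @param fed,unfed lipidome tables (see [normalize_to_standard()]).
#' @return data frame with columns `class`, `fed`, `unfed`, `ratio`, sorted
#'   by fed intensity, descending (`NA` fed last).
#' @export
compare_conditions <- function(fed, unfed) {
  a <- aggregate_by_class(fed)
  b <- aggregate_by_class(unfed)
  out <- merge(a[, c("class", "normalized_intensity")],
               b[, c("class", "normalized_intensity")],
               by = "class", all = TRUE, suffixes = c("_fed", "_unfed"))
  names(out) <- c("class", "fed", "unfed")
  out$ratio <- ifelse(is.na(out$fed) | is.na(out$unfed) | out$unfed == 0,
                      NA_real_, out$fed / out$unfed)
  out <- out[order(-ifelse(is.na(out$fed), -Inf, out$fed)), ]
  rownames(out) <- NULL
  out
}
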