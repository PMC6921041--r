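#' Validate an OTU count table
#'
#' A count table is an integer matrix of non-negative counts with OTUs as
#' rows and samples as columns, carrying unique row and column names.
#' Violations are reported with the offending OTU/sample so that malformed
#' input files can be traced to the cell.
#'
#' @param counts Matrix of counts, rows = OTUs, columns = samples.
#' @return The validated matrix (invisibly unchanged), in storage mode integer.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("count table must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table must carry OTU rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated OTU id: ",
         rownames(counts)[anyDuplicated(rownames(counts))], call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated sample id: ",
         colnames(counts)[anyDuplicated(colnames(counts))], call. = FALSE)
  }
  if (!is.numeric(counts)) stop("count table entries must be numeric", call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("invalid count %s at OTU '%s', sample '%s' (must be a non-negative integer)",
                 format(counts[bad[1]]), rownames(counts)[i[1]], colnames(counts)[i[2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table
#'
#' Reads a wide-format count table: tab-separated with the first column
#' holding OTU ids and the header row holding sample ids, or a BIOM file
#' (requires the biomformat package). Row and column order are preserved.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"tsv"`, `"biom"`. `"auto"` treats files
#'   ending in `.biom` as BIOM and everything else as TSV.
#' @return A validated integer matrix (OTUs x samples).
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(validate_count_table(m))
  }
  tb <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(tb) < 2) stop("count table needs an OTU id column plus >= 1 sample", call. = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  validate_count_table(m)
}

#' Write an OTU count table to TSV
#'
#' Inverse of [read_count_table()]: first column `otu_id`, one sample per
#' remaining column. `read_count_table(write_count_table(x, p))` returns `x`.
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  tb <- tibble::as_tibble(counts, rownames = "otu_id")
  write_table(tb, path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `plot_id`, `tree_species`,
#' `plot_richness`, `replicate`. Richness must come from the broken-stick
#' set \{1, 2, 4, 8, 16\}, replicates run 1-5, and each
#' (plot, species, replicate) triple must be unique.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble of sample records, one row per soil sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_sample_metadata(tb)
}

#' Validate a sample metadata table
#'
#' @param metadata Data frame of sample records (see [read_sample_metadata()]).
#' @return A validated tibble with typed columns.
#' @export
validate_sample_metadata <- function(metadata) {
  required <- c("sample_id", "plot_id", "tree_species", "plot_richness", "replicate")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         "; expected header: ", paste(required, collapse = ", "), call. = FALSE)
  }
  tb <- tibble::as_tibble(metadata) |>
    dplyr::mutate(
      sample_id = as.character(.data$sample_id),
      plot_id = as.character(.data$plot_id),
      tree_species = as.character(.data$tree_species),
      plot_richness = as.integer(.data$plot_richness),
      replicate = as.integer(.data$replicate)
    )
  if (anyDuplicated(tb$sample_id)) {
    stop("duplicated sample_id: ", tb$sample_id[anyDuplicated(tb$sample_id)], call. = FALSE)
  }
  bad_rich <- setdiff(unique(tb$plot_richness), RICHNESS_LEVELS)
  if (length(bad_rich) > 0) {
    stop("plot_richness outside {1,2,4,8,16}: ", paste(bad_rich, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tb$replicate)) || any(tb$replicate < 1L | tb$replicate > 5L)) {
    stop("replicate must be an integer in 1..5", call. = FALSE)
  }
  key <- paste(tb$plot_id, tb$tree_species, tb$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tb[anyDuplicated(key), ]
    stop(sprintf("duplicate (plot, species, replicate): (%s, %s, %d)",
                 d$plot_id[1], d$tree_species[1], d$replicate[1]), call. = FALSE)
  }
  tb
}

#' Read an OTU functional-guild map
#'
#' Expects a TSV with columns `otu_id` and `guild`. Guild strings outside the
#' closed set (saprotroph, ectomycorrhizal, arbuscular_mycorrhizal,
#' plant_pathogen, unknown, other) are coerced to `"other"` with a warning;
#' OTUs absent from the map resolve to `"unknown"` via [guild_of()].
#'
#' @param path Path to the guild TSV.
#' @return A tibble with columns `otu_id`, `guild`.
#' @export
read_guild_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("otu_id", "guild")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    stop("guild map is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown_strings <- setdiff(unique(tb$guild), GUILD_LEVELS)
  if (length(unknown_strings) > 0) {
    warning("guild string(s) outside the known set coerced to 'other': ",
            paste(unknown_strings, collapse = ", "), call. = FALSE)
    tb$guild[tb$guild %in% unknown_strings] <- "other"
  }
  tibble::tibble(otu_id = as.character(tb$otu_id), guild = tb$guild)
}

#' Look up guilds for OTU ids
#'
#' @param guilds Guild tibble from [read_guild_map()] (or compatible).
#' @param otu_ids Character vector of OTU ids.
#' @return Character vector of guilds; ids absent from the map give `"unknown"`.
#' @export
guild_of <- function(guilds, otu_ids) {
  g <- guilds$guild[match(otu_ids, guilds$otu_id)]
  g[is.na(g)] <- "unknown"
  g
}

#' Write a result table as TSV
#'
#' Deterministic serialization used for all pipeline outputs: UTF-8 TSV with
#' a header row, rows and columns in the order given, and numeric columns
#' rendered at 6 significant digits so repeated writes are byte-identical.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (!is.data.frame(x)) stop("x must be a data frame", call. = FALSE)
  out <- x
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      out[[j]] <- ifelse(is.na(col), "NA",
                         ifelse(col == round(col) & abs(col) < 1e15,
                                format(col, scientific = FALSE, trim = TRUE),
                                formatC(col, digits = 6, format = "g")))
    } else if (is.factor(col)) {
      out[[j]] <- as.character(col)
    }
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out) > 0) do.call(paste, c(unname(as.list(out)), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by readr.
#' @export
read_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}
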