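#' Read and write plate tables
#'
#' Plates are stored as long-format CSV (comma-separated, header row, '.'
#' decimal, UTF-8) with plate-level metadata in commented `# key: value`
#' header lines, so a write/read cycle is lossless for both reads and
#' metadata.
#'
#' @param plate A `plate_table`.
#' @param path File path.
#' @return `write_plate` returns `path` invisibly; `read_plate` returns a
#'   `plate_table`.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_table"))
  md <- attr(plate, "metadata")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(md)) {
    val <- md[[key]]
    if (is.null(val)) next
    writeLines(sprintf("# %s: %s", key,
                       format(val, digits = 15, scientific = TRUE)), con)
  }
  write.csv(as.data.frame(plate), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  md <- list()
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      md[[key]] <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE"))
        as.logical(val) else val
    }
  }
  df <- read.csv(textConnection(lines[setdiff(seq_along(lines), hdr)]),
                 stringsAsFactors = FALSE)
  need <- c("well", "condition", "conc_M", "replicate", "time_s",
            "polarization_mP", "blank")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("plate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$blank <- as.logical(df$blank)
  new_plate_table(df, md)
}
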