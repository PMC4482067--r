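#' Define the rigid stem / helix path / tip tripartition of one helix
#'
#' A pivoting helix is analyzed as (i) a short rigid stem used as the
#' superposition frame, (ii) the helix path running from the stem toward
#' the terminal loop along which deviation is profiled, and (iii) the tip
#' (final-loop) residue whose displacement quantifies the motion.
#'
#' Residue numbers refer to the reference numbering where one has been
#' applied (see [apply_numbering()]) and to author numbering otherwise.
#' Ranges are inclusive on both ends.
#'
#' @param helix_id label, e.g. `"h28"` or `"H76"`.
#' @param chain chain identifier.
#' @param stem_ranges integer vector of stem residue numbers (both
#'   strands), or a range string such as `"10-15,88-93"`.
#' @param helix_path ordered integer vector of residue numbers from stem
#'   toward the terminal loop, or a range string.
#' @param tip_residue designated final-loop residue; defaults to the last
#'   element of `helix_path`.
#' @return a `stem_definition`.
#' @export
stem_definition <- function(helix_id, chain, stem_ranges, helix_path,
                            tip_residue = NULL) {
  stem <- parse_ranges(stem_ranges)
  path <- parse_ranges(helix_path)
  path_beyond <- setdiff(path, stem)
  if (length(path_beyond) == 0) {
    stop("helix_path lies entirely within the stem for ", helix_id,
         call. = FALSE)
  }
  if (is.null(tip_residue)) tip_residue <- path[length(path)]
  structure(list(helix_id = helix_id, chain = chain, stem = stem,
                 helix_path = path, tip_residue = as.integer(tip_residue)),
            class = "stem_definition")
}

#' @export
print.stem_definition <- function(x, ...) {
  cat("stem_definition ", x$helix_id, " (chain ", x$chain, "): stem ",
      format_ranges(x$stem), ", path ", format_ranges(x$helix_path),
      ", tip ", x$tip_residue, "\n", sep = "")
  invisible(x)
}

# "10-15,88-93" -> c(10:15, 88:93); numeric vectors pass through.
parse_ranges <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(gsub("\\s", "", x), ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
  as.integer(out)
}

# Compress an integer vector back into "a-b,c-d" form (order preserved
# only across runs; used for reports).
format_ranges <- function(v) {
  v <- as.integer(v)
  if (length(v) == 0) return("")
  breaks <- c(0, which(diff(v) != 1), length(v))
  paste(vapply(seq_len(length(breaks) - 1), function(i) {
    seg <- v[(breaks[i] + 1):breaks[i + 1]]
    if (length(seg) == 1) as.character(seg)
    else paste0(seg[1], "-", seg[length(seg)])
  }, character(1)), collapse = ",")
}

#' Read a stem catalog
#'
#' Tab-separated with header
#' `helix_id  chain  stem_ranges  path_ranges  tip_residue`; ranges are
#' comma-separated inclusive `start-end` lists.
#'
#' @param path TSV file path.
#' @return named list of `stem_definition` objects.
#' @export
read_stem_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stems <- lapply(seq_len(nrow(df)), function(i) {
    stem_definition(df$helix_id[i], df$chain[i], df$stem_ranges[i],
                    df$path_ranges[i],
                    if ("tip_residue" %in% names(df)) df$tip_residue[i] else NULL)
  })
  names(stems) <- df$helix_id
  stems
}

#' Write a stem catalog
#'
#' @param stems named list of `stem_definition` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_stem_catalog <- function(stems, path) {
  df <- do.call(rbind, lapply(stems, function(s) {
    data.frame(helix_id = s$helix_id, chain = s$chain,
               stem_ranges = format_ranges(s$stem),
               path_ranges = format_ranges(s$helix_path),
               tip_residue = s$tip_residue, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
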