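#' Coupled-motion (cascade) table
#'
#' Quantifies how much of a downstream helix's motion is inherited from an
#' upstream primary pivot.  Each downstream helix's tip displacement is
#' measured twice: once after aligning the two states on the upstream
#' helix's stem (so the upstream hinge's motion carries through) and once
#' after aligning on the downstream helix's own stem (its intrinsic local
#' motion).  A ratio well above 1 marks motion induced by the upstream
#' pivot.
#'
#' @param a,b prepared `structure_model` objects.
#' @param upstream_stem a [stem_definition()] of the primary pivot helix.
#' @param downstream list of [stem_definition()] objects.
#' @param config named list overriding [pivot_config()] entries;
#'   `reporting_floor` is the noise floor used to clamp the ratio when the
#'   individual displacement is indistinguishable from noise.
#' @return a `cascade_rows` data frame: `helix_id`,
#'   `displacement_upstream_aligned`, `displacement_individual`,
#'   `amplification`, `flags`.
#' @export
cascade_table <- function(a, b, upstream_stem, downstream,
                          config = list()) {
  cfg <- merge_config(config)
  floor_ <- max(cfg$reporting_floor, 1e-6)
  up <- align_stem(a, b, upstream_stem, cfg)
  rows <- lapply(downstream, function(s) {
    out <- data.frame(helix_id = s$helix_id,
                      displacement_upstream_aligned = NA_real_,
                      displacement_individual = NA_real_,
                      amplification = NA_real_, flags = "",
                      stringsAsFactors = FALSE)
    tryCatch({
      d_up <- tip_displacement(a, up$b_aligned, s, metric = cfg$metric)
      own <- align_stem(a, b, s, cfg)
      d_own <- tip_displacement(a, own$b_aligned, s, metric = cfg$metric)
      flags <- character(0)
      denom <- d_own
      if (d_own < floor_) {
        denom <- floor_
        flags <- c(flags, "individual_below_floor")
      }
      out$displacement_upstream_aligned <- d_up
      out$displacement_individual <- d_own
      out$amplification <- d_up / denom
      out$flags <- paste(flags, collapse = ";")
      out
    }, error = function(e) {
      out$flags <- paste0("error:", conditionMessage(e))
      out
    })
  })
  out <- if (length(rows) == 0) {
    data.frame(helix_id = character(0),
               displacement_upstream_aligned = numeric(0),
               displacement_individual = numeric(0),
               amplification = numeric(0), flags = character(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "upstream") <- upstream_stem$helix_id
  class(out) <- c("cascade_rows", class(out))
  out
}

#' Pivot contact network
#'
#' Builds the edge list relating pivots: an undirected `physical_contact`
#' edge joins two pivot calls whose helix-path residues approach within
#' `cutoff` (heavy atoms), and a directed `induced_motion` edge runs from
#' the upstream helix to every downstream helix whose cascade
#' amplification exceeds `amplification_factor`.
#'
#' @param calls a `pivot_calls` data frame from [detect_pivots()].
#' @param a reference-state `structure_model`.
#' @param stems named list of [stem_definition()] objects backing `calls`.
#' @param cascade optional `cascade_rows` from [cascade_table()].
#' @param cutoff physical-contact distance cutoff in Angstrom.
#' @param amplification_factor threshold for induced-motion edges.
#' @return a `contact_edges` data frame: `a`, `b`, `kind`, `value` (the
#'   minimum atom distance for contacts, the amplification for induced
#'   motion).
#' @export
contact_network <- function(calls, a, stems, cascade = NULL, cutoff = 5.0,
                            amplification_factor = 1.5) {
  stopifnot(nrow(calls) > 0)
  ids <- calls$helix_id
  edges <- list()
  xyz_of <- lapply(ids, function(h) {
    s <- stems[[h]]
    if (is.null(s)) return(NULL)
    rows <- atom_rows_for_residues(a, s$chain, s$helix_path)
    rows <- rows[!grepl("^H|^\\dH", a$atom$elety[rows])]
    if (length(rows) == 0) NULL else coords(a, rows)
  })
  names(xyz_of) <- ids
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        xi <- xyz_of[[i]]
        xj <- xyz_of[[j]]
        if (is.null(xi) || is.null(xj)) next
        d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
        dmin <- sqrt(max(0, min(d2)))
        if (dmin < cutoff) {
          edges[[length(edges) + 1]] <- data.frame(
            a = ids[i], b = ids[j], kind = "physical_contact",
            value = dmin, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!is.null(cascade)) {
    upstream <- attr(cascade, "upstream") %||% "upstream"
    hit <- !is.na(cascade$amplification) &
      cascade$amplification > amplification_factor
    for (k in which(hit)) {
      edges[[length(edges) + 1]] <- data.frame(
        a = upstream, b = cascade$helix_id[k], kind = "induced_motion",
        value = cascade$amplification[k], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges) == 0) {
    data.frame(a = character(0), b = character(0), kind = character(0),
               value = numeric(0))
  } else do.call(rbind, edges)
  rownames(out) <- NULL
  class(out) <- c("contact_edges", class(out))
  out
}

#' Convert a contact-edge list to an igraph graph
#'
#' Physical contacts become undirected edges, induced-motion edges
#' directed ones; requires the \pkg{igraph} package.
#'
#' @param edges a `contact_edges` data frame.
#' @return an igraph graph with edge attributes `kind` and `value`.
#' @export
pivot_network_graph <- function(edges) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for graph conversion",
         call. = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = TRUE)
}
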