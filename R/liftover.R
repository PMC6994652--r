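#' Coordinate lift-over between original and modified genomes
#'
#' Applying insertions and deletions shifts coordinates, so gene models and
#' other annotations defined on the published reference must be lifted onto
#' the modified reference. [apply_variants()] returns a `coordinate_map`:
#' per-contig anchor pairs `(original_pos, modified_pos)` that are strictly
#' increasing in both coordinates, plus the intervals deleted from the
#' original and inserted into the modified sequence.
#'
#' @param map a `coordinate_map` from [apply_variants()].
#' @param contig contig id.
#' @param pos integer vector of 1-based positions to lift.
#' @param direction `"forward"` (original to modified) or `"backward"`.
#' @param mode `"strict"` returns `NA` for positions with no image (deleted
#'   original positions, inserted modified positions); `"nearest"` maps them
#'   to the last preceding position that has one.
#' @return integer vector of lifted positions (with `NA`s in strict mode).
#' @export
lift_position <- function(map, contig, pos,
                          direction = c("forward", "backward"),
                          mode = c("strict", "nearest")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(inherits(map, "coordinate_map"))
  anc <- map$anchors[map$anchors$contig == contig, , drop = FALSE]
  if (nrow(anc) == 0L) stop("contig not in coordinate map: ", contig)
  if (direction == "forward") {
    from <- anc$original_pos; to <- anc$modified_pos
    gaps <- map$deleted[map$deleted$contig == contig, , drop = FALSE]
    len <- map$original_length[[contig]]
  } else {
    from <- anc$modified_pos; to <- anc$original_pos
    gaps <- map$inserted[map$inserted$contig == contig, , drop = FALSE]
    len <- map$modified_length[[contig]]
  }
  out <- rep(NA_integer_, length(pos))
  ok <- !is.na(pos) & pos >= 1L & pos <= len
  gapped <- rep(FALSE, length(pos))
  if (nrow(gaps) > 0L && any(ok)) {
    for (i in seq_len(nrow(gaps)))
      gapped <- gapped | (ok & pos >= gaps$start[i] & pos <= gaps$end[i])
  }
  eff <- pos
  if (mode == "nearest" && any(gapped)) {
    for (i in which(gapped)) {
      g <- gaps[pos[i] >= gaps$start & pos[i] <= gaps$end, , drop = FALSE]
      eff[i] <- g$start[1L] - 1L
    }
    gapped[gapped] <- eff[gapped] < 1L
  }
  live <- ok & !gapped
  if (any(live)) {
    idx <- findInterval(eff[live], from)
    out[live] <- as.integer(eff[live] + (to[idx] - from[idx]))
  }
  out
}

#' @rdname lift_position
#' @export
write_coordinate_map <- function(map, path) {
  utils::write.table(map$anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

new_coordinate_map <- function(anchors, deleted, inserted,
                               original_length, modified_length) {
  structure(list(anchors = anchors, deleted = deleted, inserted = inserted,
                 original_length = original_length,
                 modified_length = modified_length),
            class = "coordinate_map")
}

empty_interval_df <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Lift gene models through a coordinate map
#'
#' Exon boundaries are lifted forward onto the modified genome; boundaries
#' that fall inside deleted segments are clamped to the nearest surviving
#' base. Exons whose entire span was deleted are dropped (with a warning),
#' and genes that lose all exons are removed.
#'
#' @param genes a `gene_models` data frame (see [gene_models()]).
#' @inheritParams lift_position
#' @return lifted `gene_models` data frame.
#' @export
lift_gene_models <- function(genes, map) {
  stopifnot(inherits(genes, "gene_models"))
  out <- genes
  for (ct in unique(genes$contig)) {
    sel <- genes$contig == ct
    out$start[sel] <- lift_position(map, ct, genes$start[sel],
                                    mode = "nearest")
    out$end[sel] <- lift_position(map, ct, genes$end[sel], mode = "nearest")
  }
  dead <- is.na(out$start) | is.na(out$end) | out$end < out$start
  if (any(dead)) {
    warning(sum(dead), " exon(s) lost in lift-over")
    out <- out[!dead, , drop = FALSE]
  }
  gene_models(out)
}
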