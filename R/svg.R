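# EasyFig-style stacked comparison figure, written as deterministic SVG
# text (byte-identical across runs for the same input).

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt2 <- function(x) sprintf("%.2f", x)

# identity in [min_identity, 100] -> grey shade
shade_for <- function(identity, min_identity) {
  f <- (identity - min_identity) / max(100 - min_identity, 1e-9)
  f <- min(max(f, 0), 1)
  g <- round(210 - f * 160)
  sprintf("rgb(%d,%d,%d)", g, g, g)
}

feature_arrow <- function(x0, x1, y, h, strand, fill) {
  head <- min(0.35 * (x1 - x0), 8)
  pts <- if (strand == "-") {
    rbind(c(x1, y - h / 2), c(x0 + head, y - h / 2), c(x0, y),
          c(x0 + head, y + h / 2), c(x1, y + h / 2))
  } else {
    rbind(c(x0, y - h / 2), c(x1 - head, y - h / 2), c(x1, y),
          c(x1 - head, y + h / 2), c(x0, y + h / 2))
  }
  sprintf('<polygon points="%s" fill="%s" stroke="black" stroke-width="0.5"/>',
          paste(apply(pts, 1L, function(p)
            paste(fmt2(p[1]), fmt2(p[2]), sep = ",")), collapse = " "),
          fill)
}

#' Render the stacked region comparison as SVG (plus a blocks TSV)
#'
#' One horizontal map per region in display order, labelled with record
#' id and 1-based source coordinates; features drawn as strand-aware
#' arrows with the anchor gene highlighted; identity blocks between
#' consecutive rows drawn as trapezoids shaded by percent identity
#' (inverted blocks cross and are outlined in red). Output is
#' deterministic for fixed input.
#'
#' @param regions list of `context_region` in display order
#' @param blocks output of [compare_regions()] on the same regions
#' @param svg_path output SVG file
#' @param tsv_path optional blocks TSV ([write_blocks()])
#' @param width drawing width in px
#' @param min_identity shade floor, should match the comparison call
#' @return `svg_path`, invisibly
#' @export
render_comparison <- function(regions, blocks, svg_path, tsv_path = NULL,
                              width = 1000, min_identity = 60) {
  stopifnot(length(regions) >= 1L)
  margin <- 140
  row_h <- 110
  maxlen <- max(vapply(regions, function(r) nchar(r$sequence), 0L))
  scale <- (width - margin - 20) / maxlen
  height <- row_h * length(regions) + 30
  ids <- vapply(regions, function(r) r$region_id, "")
  ys <- 60 + row_h * (seq_along(regions) - 1L)
  el <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  round(width), round(height)),
          '<rect width="100%" height="100%" fill="white"/>')
  xpos <- function(bp) margin + bp * scale
  # inter-row blocks first (under the maps)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ra <- match(b$region_a, ids); rb <- match(b$region_b, ids)
    if (is.na(ra) || is.na(rb) || abs(ra - rb) != 1L) next
    ya <- ys[ra] + 8; yb <- ys[rb] - 8
    x1 <- xpos(b$a_start); x2 <- xpos(b$a_end)
    if (b$orientation == "same") {
      x3 <- xpos(b$b_end); x4 <- xpos(b$b_start)
    } else {
      x3 <- xpos(b$b_start); x4 <- xpos(b$b_end)
    }
    el <- c(el, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" fill-opacity="0.75" stroke="%s" stroke-width="0.5"/>',
      fmt2(x1), fmt2(ya), fmt2(x2), fmt2(ya), fmt2(x3), fmt2(yb),
      fmt2(x4), fmt2(yb), shade_for(b$pct_identity, min_identity),
      if (b$orientation == "inverted") "red" else "none"))
  }
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    y <- ys[i]
    L <- nchar(r$sequence)
    el <- c(el, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1.5"/>',
      fmt2(xpos(0)), fmt2(y), fmt2(xpos(L)), fmt2(y)))
    el <- c(el, sprintf(
      '<text x="10" y="%s" font-family="sans-serif" font-size="11">%s</text>',
      fmt2(y - 14), svg_esc(r$record_id)))
    el <- c(el, sprintf(
      '<text x="10" y="%s" font-family="sans-serif" font-size="9" fill="#555">%s..%s (%d bp)</text>',
      fmt2(y - 2), format(r$region_interval[1] + 1L, scientific = FALSE),
      format(r$region_interval[2], scientific = FALSE), L))
    fts <- r$features
    for (j in seq_len(nrow(fts))) {
      f <- fts[j, ]
      is_anchor <- f$start >= r$anchor_interval[1] - 1L &&
        f$end <= r$anchor_interval[2] + 1L &&
        (f$end - f$start) >= 0.9 * diff(r$anchor_interval)
      fill <- if (is_anchor) "#d62728"
              else if (f$kind == "CDS") "#1f77b4" else "#9edae5"
      el <- c(el, feature_arrow(xpos(f$start), xpos(f$end), y, 12,
                                f$strand, fill))
    }
    # explicit anchor marker when the anchor has no matching feature
    el <- c(el, sprintf(
      '<rect x="%s" y="%s" width="%s" height="3" fill="#d62728"/>',
      fmt2(xpos(r$anchor_interval[1])), fmt2(y + 10),
      fmt2(max(diff(r$anchor_interval) * scale, 1))))
  }
  el <- c(el, "</svg>")
  writeLines(el, svg_path)
  if (!is.null(tsv_path))
    write_blocks(blocks, tsv_path,
                 params = list(min_identity = min_identity))
  invisible(svg_path)
}
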