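# Signed, motif-oriented distance statistics and ordering classification
# of factor summits around the oriented CTCF motif; TAD relative-position
# statistic.

#' Signed motif-oriented distance
#'
#' Distance of a position from an oriented motif center, on the motif's
#' own axis: negative values are 5' of the G-rich motif direction. For a
#' `+` oriented site this is `position - center`; for `-`,
#' `center - position`.
#'
#' @param position absolute bp (vectorised).
#' @param center motif center, absolute bp.
#' @param orientation `"+"` or `"-"` motif orientation.
#' @return signed distance in bp.
#' @export
oriented_distance <- function(position, center, orientation) {
  stopifnot(all(orientation %in% c("+", "-")))
  ifelse(orientation == "+", position - center, center - position)
}

#' Oriented summit offsets of each factor around its site's motif
#'
#' For every oriented site, the nearest summit of each factor is found and
#' its signed motif-oriented offset computed. Sites where any factor's
#' nearest summit lies outside `±flank` are excluded (and counted), as are
#' sites missing a factor on the same chromosome.
#'
#' @param sites oriented-site data frame (`site_id`, `chrom`, `center`,
#'   `orientation`).
#' @param peaks_by_factor named list of peak data frames with `summit`.
#' @param flank inclusion window around the motif center (default 100 bp).
#' @return list with `offsets`: one row per retained site, columns
#'   `site_id`, `orientation`, then `<factor>` (oriented offset) and
#'   `<factor>_raw` (un-oriented `summit - center` on the genome's
#'   + strand) per factor; and `n_excluded`.
#' @export
site_offsets <- function(sites, peaks_by_factor, flank = 100) {
  stopifnot(nrow(sites) >= 1, !is.null(names(peaks_by_factor)))
  out <- data.frame(site_id = sites$site_id, orientation = sites$orientation)
  for (f in names(peaks_by_factor)) {
    p <- peaks_by_factor[[f]]
    stopifnot(!is.null(p$summit))
    raw <- rep(NA_real_, nrow(sites))
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      su <- sort(p$summit[p$chrom == ch])
      if (length(su) == 0) next
      ctr <- sites$center[si]
      i <- findInterval(ctr, su)
      lo <- pmax(i, 1); hi <- pmin(i + 1, length(su))
      nearest <- ifelse(i < 1, su[hi],
                 ifelse(i >= length(su), su[lo],
                        ifelse(ctr - su[lo] <= su[hi] - ctr, su[lo], su[hi])))
      raw[si] <- nearest - ctr
    }
    out[[paste0(f, "_raw")]] <- raw
    out[[f]] <- oriented_distance(sites$center + raw, sites$center,
                                  sites$orientation)
  }
  fac <- names(peaks_by_factor)
  off <- as.matrix(out[, fac, drop = FALSE])
  keep <- stats::complete.cases(off) & apply(abs(off) <= flank, 1, all)
  list(offsets = out[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Per-factor summaries of oriented and un-oriented offset distributions
#'
#' @param offsets the `offsets` element of [site_offsets()].
#' @param factors which factors to summarise (default: all present).
#' @return data frame with one row per factor and mode (`oriented`,
#'   `unoriented`): `median`, `q25`, `q75`, `n`.
#' @export
distance_summaries <- function(offsets, factors = NULL) {
  if (is.null(factors))
    factors <- setdiff(names(offsets),
                       c("site_id", "orientation",
                         grep("_raw$", names(offsets), value = TRUE)))
  do.call(rbind, lapply(factors, function(f) {
    do.call(rbind, lapply(c("oriented", "unoriented"), function(mode) {
      v <- if (mode == "oriented") offsets[[f]] else offsets[[paste0(f, "_raw")]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(factor = f, mode = mode, median = q[2], q25 = q[1],
                 q75 = q[3], n = length(v))
    }))
  }))
}

#' Ordering label of factor summits along the oriented motif axis
#'
#' Factors are sorted ascending by signed offset; exact ties are broken
#' alphabetically and flagged. The label joins factor names with `-`,
#' 5'-most first.
#'
#' @param offsets data frame with one column per factor (oriented offsets);
#'   extra columns (`site_id`, `orientation`, `*_raw`) are ignored.
#' @param factors factor columns to order (default: all offset columns).
#' @param oriented use oriented offsets (TRUE) or the `_raw` un-oriented
#'   offsets (FALSE).
#' @return data frame `site_id`, `order` (label), `tie` (logical).
#' @export
classify_order <- function(offsets, factors = NULL, oriented = TRUE) {
  if (is.null(factors))
    factors <- setdiff(names(offsets),
                       c("site_id", "orientation",
                         grep("_raw$", names(offsets), value = TRUE)))
  stopifnot(length(factors) >= 2)
  cols <- if (oriented) factors else paste0(factors, "_raw")
  m <- as.matrix(offsets[, cols, drop = FALSE])
  colnames(m) <- factors
  res <- apply(m, 1, function(v) {
    o <- order(v, factors)  # ties broken alphabetically
    c(paste(factors[o], collapse = "-"), as.character(anyDuplicated(v) > 0))
  })
  data.frame(
    site_id = if (!is.null(offsets$site_id)) offsets$site_id
              else seq_len(nrow(offsets)),
    order = res[1, ], tie = as.logical(res[2, ]))
}

#' Enrichment of the canonical ordering after motif orientation
#'
#' Compares the fraction of sites showing the canonical factor order
#' before vs after orienting by the motif, with Fisher's exact test on the
#' 2x2 table (canonical vs not x before vs after).
#'
#' @param before,after character vectors of ordering labels (or the data
#'   frames from [classify_order()]).
#' @param canonical the canonical ordering label (default
#'   `"TOP2B-CTCF-RAD21"`).
#' @return list: `fraction_before`, `fraction_after`, `counts_before`,
#'   `counts_after` (tables over labels), `p` (Fisher).
#' @export
order_enrichment <- function(before, after,
                             canonical = "TOP2B-CTCF-RAD21") {
  if (is.data.frame(before)) before <- before$order
  if (is.data.frame(after)) after <- after$order
  if (length(before) == 0 || length(after) == 0)
    stop("empty ordering counts")
  a <- sum(before == canonical); b <- sum(after == canonical)
  tab <- matrix(c(a, length(before) - a, b, length(after) - b), nrow = 2)
  list(fraction_before = a / length(before),
       fraction_after = b / length(after),
       counts_before = table(before), counts_after = table(after),
       p = stats::fisher.test(tab)$p.value)
}

#' Relative position of sites within their topological domain
#'
#' For a site whose anchor coordinate falls inside a domain, the relative
#' position is `(anchor - domain_center + size/2) / size`, i.e. 0 at the
#' 5' border, 0.5 at the center, 1 at the 3' border. Sites in no domain
#' get `NA`.
#'
#' @param anchors data frame with `chrom` and `pos` (absolute bp; use the
#'   motif center when available, else the peak summit).
#' @param domains disjoint interval data frame of domains.
#' @return numeric vector in \[0, 1\] (or `NA`), one per anchor.
#' @export
relative_domain_position <- function(anchors, domains) {
  validate_intervals(domains, what = "domain")
  out <- rep(NA_real_, nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    d <- d[order(d$start), , drop = FALSE]
    ai <- which(anchors$chrom == ch)
    pos <- anchors$pos[ai]
    j <- findInterval(pos, d$start)
    inside <- j >= 1 & pos < d$end[pmax(j, 1)]
    jj <- j[inside]
    size <- d$end[jj] - d$start[jj]
    ctr <- (d$start[jj] + d$end[jj]) / 2
    out[ai[inside]] <- (pos[inside] - ctr + size / 2) / size
  }
  out
}

#' Edge-vs-center density ratio of relative domain positions
#'
#' Summary used for border-enrichment readouts: density of positions in
#' `[0, 0.1] U [0.9, 1]` divided by density in `[0.45, 0.55]`.
#'
#' @param relpos numeric vector from [relative_domain_position()].
#' @return the density ratio (edge bins total 0.2 of the axis, center 0.1).
#' @export
border_density_ratio <- function(relpos) {
  relpos <- relpos[!is.na(relpos)]
  edge <- mean(relpos <= 0.1 | relpos >= 0.9) / 0.2
  center <- mean(relpos >= 0.45 & relpos <= 0.55) / 0.1
  edge / center
}
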