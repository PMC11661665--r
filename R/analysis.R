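# The contact-map analysis protocol: per-frame Boolean base-pairing maps,
# contact persistence and stable contacts (strictly over the 50% threshold),
# upper-triangular Hamming distances, average-linkage (UPGMA) hierarchical
# clustering with a deterministic tie-break, pseudoknot (crossing-pair)
# detection, contact-span statistics and overlap with a dot-bracket
# secondary structure.

pair_key <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  paste(pairs[, 1], pairs[, 2])
}

#' Boolean contact map of one frame
#'
#' @param frame an \code{\link{hb_frame}} or an m x 2 matrix of 0-based index
#'   pairs.
#' @param n chain length.
#' @return object of class \code{contact_map}: upper-triangular pair set
#'   (i < j, duplicates collapsed) plus the chain length.
#' @export
contact_map <- function(frame, n) {
  pairs <- if (inherits(frame, "hb_frame")) frame$pairs else normalize_pairs(frame)
  if (nrow(pairs) && any(pairs >= n | pairs < 0))
    stop(sprintf("pair index out of range for chain length %d", n))
  structure(list(n = as.integer(n), contacts = pairs), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> n = %d, %d contacts\n", x$n, nrow(x$contacts)))
  invisible(x)
}

#' Per-frame contact-map series
#'
#' @param maps list of \code{\link{contact_map}}s (or \code{\link{hb_frame}}s,
#'   converted with chain length \code{n}).
#' @param n shared chain length.
#' @return object of class \code{contact_series}.
#' @export
contact_series <- function(maps, n) {
  maps <- lapply(maps, function(m) {
    if (inherits(m, "contact_map")) {
      if (m$n != n) stop("all maps must share the chain length n")
      m
    } else contact_map(m, n)
  })
  structure(list(maps = maps, n = as.integer(n)), class = "contact_series")
}

#' Contact persistence across a trajectory
#'
#' Fraction of frames containing each pair that occurs at least once.
#'
#' @param series a \code{\link{contact_series}} with at least one frame.
#' @return data.frame with columns \code{i}, \code{j}, \code{fraction},
#'   sorted by (i, j).
#' @export
persistence <- function(series) {
  stopifnot(inherits(series, "contact_series"), length(series$maps) >= 1L)
  keys <- unlist(lapply(series$maps, function(m) pair_key(m$contacts)))
  if (!length(keys))
    return(data.frame(i = integer(0), j = integer(0), fraction = numeric(0)))
  tab <- table(keys)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    fraction = as.numeric(tab) / length(series$maps))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Stable contacts: pairs conserved over a persistence threshold
#'
#' A contact is stable when its persistence is strictly greater than the
#' threshold ("conserved over 50%" reads as > 0.5, so a pair present in
#' exactly half the frames is excluded).
#'
#' @param series a \code{\link{contact_series}}.
#' @param threshold persistence threshold in (0, 1].
#' @return a \code{\link{contact_map}} of the stable pairs.
#' @export
stable_contacts <- function(series, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  p <- persistence(series)
  keep <- p$fraction > threshold
  contact_map(cbind(p$i[keep], p$j[keep]), series$n)
}

#' Hamming distance between two contact maps
#'
#' Number of differing entries of the upper-triangular Boolean matrices,
#' i.e. the size of the symmetric difference of the contact sets.
#'
#' @param a,b \code{\link{contact_map}}s over the same chain length.
#' @return non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  if (a$n != b$n)
    stop(sprintf("chain lengths differ: %d vs %d", a$n, b$n))
  ka <- pair_key(a$contacts); kb <- pair_key(b$contacts)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Pairwise Hamming-distance matrix over a contact series
#'
#' @param series a \code{\link{contact_series}}.
#' @param stride keep every stride-th frame.
#' @param normalized divide by the number of upper-triangular entries
#'   n(n-1)/2 (off by default: the metric is the raw count of differing
#'   entries).
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(series, stride = 1L, normalized = FALSE) {
  stopifnot(inherits(series, "contact_series"), stride >= 1L)
  maps <- series$maps[seq(1L, length(series$maps), by = stride)]
  m <- length(maps)
  keys <- lapply(maps, function(x) pair_key(x$contacts))
  D <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (b > a) {
    d <- length(setdiff(keys[[a]], keys[[b]])) +
      length(setdiff(keys[[b]], keys[[a]]))
    D[a, b] <- d; D[b, a] <- d
  }
  if (normalized) D <- D / (series$n * (series$n - 1) / 2)
  D
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Unweighted average inter-cluster distances; at every stage the closest
#' active pair merges, ties broken deterministically by the lexicographically
#' smallest pair of lowest cluster indices (clusters numbered 1..n for the
#' leaves, then n+1, n+2, ... in creation order). Merge heights are
#' non-decreasing for a metric input.
#'
#' @param dist square symmetric non-negative matrix with zero diagonal.
#' @return object of class \code{dendrogram_al}: \code{merges} data.frame
#'   (a, b, height, size) and \code{leaf_count}.
#' @export
average_linkage <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n) stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > 0) stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dist < 0)) stop("distances must be non-negative")
  active <- seq_len(n)          # cluster ids, 1..n leaves
  sizes <- rep(1L, n)
  names(sizes) <- active
  D <- dist
  rownames(D) <- colnames(D) <- active
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0),
                       size = integer(0))
  next_id <- n
  while (length(active) > 1L) {
    m <- length(active)
    dmin <- Inf; pick <- NULL
    for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
      ia <- min(active[p], active[q]); ib <- max(active[p], active[q])
      dv <- D[as.character(active[p]), as.character(active[q])]
      if (dv < dmin ||
          (dv == dmin && (ia < pick[1] || (ia == pick[1] && ib < pick[2])))) {
        dmin <- dv; pick <- c(ia, ib)
      }
    }
    a <- pick[1]; b <- pick[2]
    next_id <- next_id + 1L
    sa <- sizes[as.character(a)]; sb <- sizes[as.character(b)]
    others <- setdiff(active, c(a, b))
    newd <- vapply(others, function(o) {
      (sa * D[as.character(a), as.character(o)] +
         sb * D[as.character(b), as.character(o)]) / (sa + sb)
    }, numeric(1))
    merges <- rbind(merges, data.frame(a = a, b = b, height = dmin,
                                       size = as.integer(sa + sb)))
    active <- c(others, next_id)
    sizes <- c(sizes, stats::setNames(sa + sb, next_id))
    D2 <- matrix(0, length(active), length(active),
                 dimnames = list(active, active))
    if (length(others)) {
      D2[seq_along(others), seq_along(others)] <-
        D[as.character(others), as.character(others)]
      D2[length(active), seq_along(others)] <- newd
      D2[seq_along(others), length(active)] <- newd
    }
    D <- D2
  }
  structure(list(merges = merges, leaf_count = n), class = "dendrogram_al")
}

#' @export
print.dendrogram_al <- function(x, ...) {
  cat(sprintf("<dendrogram_al> %d leaves, %d merges, heights %.4g..%.4g\n",
              x$leaf_count, nrow(x$merges), min(x$merges$height),
              max(x$merges$height)))
  invisible(x)
}

#' Newick-like nested-text export of a dendrogram
#'
#' @param dendro a \code{dendrogram_al}.
#' @return single Newick string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(dendro) {
  n <- dendro$leaf_count
  lab <- as.list(paste0("L", seq_len(n)))
  h <- as.list(rep(0, n))
  for (k in seq_len(nrow(dendro$merges))) {
    mk <- dendro$merges[k, ]
    ba <- (mk$height - h[[mk$a]]) / 2; bb <- (mk$height - h[[mk$b]]) / 2
    lab[[n + k]] <- sprintf("(%s:%g,%s:%g)", lab[[mk$a]], ba, lab[[mk$b]], bb)
    h[[n + k]] <- mk$height
  }
  paste0(lab[[n + nrow(dendro$merges)]], ";")
}

#' Crossing (pseudoknot) contact pairs
#'
#' All pairs of contacts ((i, j), (k, l)) that interleave, i < k < j < l:
#' the standard criterion for a pseudoknot in a secondary-structure contact
#' set.
#'
#' @param map a \code{\link{contact_map}}.
#' @return data.frame with columns \code{i}, \code{j}, \code{k}, \code{l},
#'   one row per crossing pair-pair.
#' @export
crossing_pairs <- function(map) {
  p <- map$contacts
  m <- nrow(p)
  out <- list()
  if (m >= 2L) {
    ord <- order(p[, 1], p[, 2])
    p <- p[ord, , drop = FALSE]
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
      if (i < k && k < j && j < l)
        out[[length(out) + 1L]] <- c(i, j, k, l)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      l = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("i", "j", "k", "l")
  df
}

#' Histogram of contact sequence separations
#'
#' @param map a \code{\link{contact_map}}.
#' @return data.frame with columns \code{span} (= j - i) and \code{count};
#'   total count equals the number of contacts.
#' @export
contact_span_distribution <- function(map) {
  if (!nrow(map$contacts))
    return(data.frame(span = integer(0), count = integer(0)))
  sp <- map$contacts[, 2] - map$contacts[, 1]
  tab <- table(sp)
  data.frame(span = as.integer(names(tab)), count = as.integer(tab))
}

#' Parse a dot-bracket secondary structure into base pairs
#'
#' Supports nested bracket tiers \code{()}, \code{[]}, \code{\{\}} and
#' \code{<>} (extra tiers encode pseudoknots). Unbalanced brackets raise an
#' error naming the offending position (1-based).
#'
#' @param structure dot-bracket string.
#' @return m x 2 matrix of 0-based pairs (i < j).
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  open <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")
  stacks <- lapply(names(open), function(...) integer(0))
  names(stacks) <- names(open)
  pairs <- list()
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch %in% names(open)) {
      stacks[[ch]] <- c(stacks[[ch]], pos)
    } else if (ch %in% open) {
      op <- names(open)[match(ch, open)]
      if (!length(stacks[[op]]))
        stop(sprintf("unbalanced '%s' at position %d", ch, pos))
      i <- stacks[[op]][length(stacks[[op]])]
      stacks[[op]] <- stacks[[op]][-length(stacks[[op]])]
      pairs[[length(pairs) + 1L]] <- c(i - 1L, pos - 1L)
    } else if (ch != "." && ch != "-") {
      stop(sprintf("unexpected character '%s' at position %d", ch, pos))
    }
  }
  for (op in names(stacks)) {
    if (length(stacks[[op]]))
      stop(sprintf("unbalanced '%s' at position %d", op,
                   stacks[[op]][length(stacks[[op]])]))
  }
  normalize_pairs(if (length(pairs)) do.call(rbind, pairs)
                  else matrix(integer(0), ncol = 2))
}

#' Overlap of a contact map with a dot-bracket structure
#'
#' Fraction of the structure's base pairs also present in the map:
#' |map contacts intersect structure pairs| / |structure pairs|.
#'
#' @param map a \code{\link{contact_map}} (e.g. stable MD contacts).
#' @param structure dot-bracket string of length \code{map$n}.
#' @return fraction in [0, 1] (0 when the structure has no pairs).
#' @export
dotbracket_overlap <- function(map, structure) {
  if (nchar(structure) != map$n)
    stop(sprintf("structure length (%d) must equal chain length (%d)",
                 nchar(structure), map$n))
  ref <- parse_dotbracket(structure)
  if (!nrow(ref)) return(0)
  length(intersect(pair_key(map$contacts), pair_key(ref))) / nrow(ref)
}

#' Export stable contacts as chord-diagram data (JSON)
#'
#' Pair list plus persistence weights, the data behind a chord-diagram
#' rendering (plotting itself is out of scope).
#'
#' @param series a \code{\link{contact_series}}.
#' @param path output JSON path.
#' @param threshold persistence threshold for inclusion.
#' @return the path, invisibly.
#' @export
export_chord_json <- function(series, path, threshold = 0.5) {
  p <- persistence(series)
  p <- p[p$fraction > threshold, , drop = FALSE]
  jsonlite::write_json(list(n = series$n,
                            contacts = p),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
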