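#' Generate a restriction fragment map
#'
#' Tiles every chromosome of a genome spec with restriction fragments whose
#' lengths are drawn i.i.d. as 100 + Exponential(mean - 100) bp (the last
#' fragment is truncated at the chromosome end). Each fragment end carries a
#' GC fraction for its terminal min(200 bp, fragment length) region, drawn
#' from the spec's clipped-Gaussian GC model, and a mappability flag
#' (`TRUE` by default).
#'
#' Coordinates are 0-based half-open; fragments tile each chromosome with no
#' gaps or overlaps.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer master seed; the map is deterministic given the seed.
#' @return A `fragment_map`: a `data.table` with columns species, chrom,
#'   frag_id (1-based, unique within the map), start, end, length,
#'   gc_left, gc_right, mappable, plus attributes `species_label` and
#'   `chromosome_lengths`.
#' @export
generate_fragment_map <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(seed, 1))
  m <- spec$mean_fragment_length
  per_chrom <- lapply(names(spec$chromosome_lengths), function(ch) {
    L <- spec$chromosome_lengths[[ch]]
    # over-draw, cut at chromosome end, truncate the last fragment
    n_guess <- max(8L, ceiling(L / m * 1.25) + 8L)
    repeat {
      lens <- if (m > 100) 100 + stats::rexp(n_guess, rate = 1 / (m - 100))
              else rep(100, n_guess)
      ends <- cumsum(lens)
      if (ends[length(ends)] >= L) break
      n_guess <- n_guess * 2L
    }
    k <- which(ends >= L)[1L]
    ends <- ends[seq_len(k)]
    ends[k] <- L
    starts <- c(0, ends[-k])
    data.table::data.table(chrom = ch, start = floor(starts), end = floor(ends))
  })
  map <- data.table::rbindlist(per_chrom)
  map[, `:=`(species = spec$species_label,
             frag_id = seq_len(.N),
             length = end - start)]
  gc_draw <- function(n) pmin(1, pmax(0, stats::rnorm(n, spec$gc_mean, spec$gc_sd)))
  map[, `:=`(gc_left = gc_draw(.N), gc_right = gc_draw(.N), mappable = TRUE)]
  data.table::setcolorder(map, c("species", "chrom", "frag_id", "start", "end",
                                 "length", "gc_left", "gc_right", "mappable"))
  cl <- spec$chromosome_lengths
  names(cl) <- names(spec$chromosome_lengths)
  data.table::setattr(map, "species_label", spec$species_label)
  data.table::setattr(map, "chromosome_lengths", cl)
  data.table::setattr(map, "class", c("fragment_map", class(map)))
  map[]
}

#' Combine per-species fragment maps into one pooled map
#'
#' Chromosome names are made unique by prefixing with the species label
#' (`"mm.chr1"`), so a two-species pool behaves like one composite genome.
#' Fragment ids are re-assigned to be unique across the pool.
#'
#' @param maps A `fragment_map` or list of them.
#' @return A pooled `fragment_map`.
#' @export
pool_fragment_maps <- function(maps) {
  if (inherits(maps, "fragment_map")) maps <- list(maps)
  cls <- list()
  parts <- lapply(maps, function(mp) {
    mp <- data.table::copy(mp)
    sp <- attr(mp, "species_label")
    cl <- attr(mp, "chromosome_lengths")
    names(cl) <- paste(sp, names(cl), sep = ".")
    cls[[sp]] <<- cl
    mp[, chrom := paste(species, chrom, sep = ".")]
    mp
  })
  pooled <- data.table::rbindlist(parts)
  pooled[, frag_id := seq_len(.N)]
  data.table::setattr(pooled, "chromosome_lengths", unlist(unname(cls)))
  data.table::setattr(pooled, "class",
                      c("fragment_map", "data.table", "data.frame"))
  pooled[]
}

#' Write / read a fragment map as BED plus a feature sidecar
#'
#' The BED file holds chrom, start, end, fragment_id; the sidecar
#' (`<path>.features.tsv`) holds fragment_id, species, length, gc_5prime_end,
#' gc_3prime_end, mappable. Coordinates are 0-based half-open as in BED.
#'
#' @param map A `fragment_map`.
#' @param path BED file path.
#' @return `read_fragment_map` returns a `fragment_map`.
#' @export
write_fragment_map <- function(map, path) {
  bed <- map[, .(chrom, start, end, frag_id)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  feat <- map[, .(frag_id, species, length,
                  gc_5prime_end = gc_left, gc_3prime_end = gc_right, mappable)]
  data.table::fwrite(feat, paste0(path, ".features.tsv"), sep = "\t")
  # sidecar with chromosome lengths so the map round-trips
  cl <- attr(map, "chromosome_lengths")
  data.table::fwrite(data.table::data.table(chrom = names(cl), length = cl),
                     paste0(path, ".chrom.sizes"), sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  bed <- data.table::fread(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "frag_id"))
  feat <- data.table::fread(paste0(path, ".features.tsv"))
  map <- feat[bed, on = "frag_id"]
  data.table::setnames(map, c("gc_5prime_end", "gc_3prime_end"),
                       c("gc_left", "gc_right"))
  data.table::setcolorder(map, c("species", "chrom", "frag_id", "start", "end",
                                 "length", "gc_left", "gc_right", "mappable"))
  szfile <- paste0(path, ".chrom.sizes")
  if (file.exists(szfile)) {
    sz <- data.table::fread(szfile, header = FALSE,
                            col.names = c("chrom", "length"))
    cl <- sz$length; names(cl) <- sz$chrom
  } else {
    cl <- map[, max(end), by = chrom][, stats::setNames(V1, chrom)]
  }
  data.table::setattr(map, "chromosome_lengths", cl)
  data.table::setattr(map, "species_label",
                      paste(unique(map$species), collapse = "+"))
  data.table::setattr(map, "class",
                      c("fragment_map", "data.table", "data.frame"))
  map[]
}

#' Fragment-end features and 20-bin quantile assignments
#'
#' Expands a fragment map to one row per fragment end (two per fragment) and
#' assigns each end to equal-occupancy quantile bins of fragment length and
#' of terminal-200-bp GC content. These feature bins index the 20x20 bias
#' matrices of [estimate_bias()].
#'
#' @param map A `fragment_map` (possibly pooled).
#' @param n_bins Number of quantile bins per feature (default 20).
#' @return A list with `fends` (data.table: species, chrom, frag_id, side
#'   ("L"/"R"), pos (the fend coordinate), length, gc, len_bin, gc_bin,
#'   mappable) and `edges` (list of length/gc bin edges).
#' @export
fend_features <- function(map, n_bins = 20L) {
  left <- map[, .(species, chrom, frag_id, side = "L", pos = start,
                  length, gc = gc_left, mappable)]
  right <- map[, .(species, chrom, frag_id, side = "R", pos = end,
                   length, gc = gc_right, mappable)]
  fends <- data.table::rbindlist(list(left, right))
  qedges <- function(x) {
    e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                names = FALSE, type = 7))
    e[1] <- -Inf; e[length(e)] <- Inf
    e
  }
  len_edges <- qedges(fends$length)
  gc_edges <- qedges(fends$gc)
  fends[, len_bin := findInterval(length, len_edges, rightmost.closed = TRUE)]
  fends[, gc_bin := findInterval(gc, gc_edges, rightmost.closed = TRUE)]
  list(fends = fends[], n_bins = as.integer(n_bins),
       edges = list(length = len_edges, gc = gc_edges))
}
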