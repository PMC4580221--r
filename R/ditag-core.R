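#' Read and write di-tag tables in a .pairs-style dialect
#'
#' Tab-separated, one record per line:
#' `readID chrom1 pos1 strand1 chrom2 pos2 strand2 frag1 frag2 [truth]`,
#' with 0-based coordinates. Header lines begin with `#` and are preserved
#' verbatim on round-trip (a `#columns:` line is written by `write_pairs`).
#'
#' @param path File path.
#' @param table A `ditag_table`.
#' @return `read_pairs` returns a `ditag_table` (possibly with extra columns
#'   such as `truth` if present in the file); `write_pairs` returns the path
#'   invisibly.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  header <- lines[hdr]
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(body)]
  cols <- c("readID", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "frag1", "frag2", "truth")
  if (!length(body)) {
    tab <- data.table::data.table(readID = character(), chrom1 = character(),
      pos1 = numeric(), strand1 = character(), chrom2 = character(),
      pos2 = numeric(), strand2 = character(), frag1 = integer(),
      frag2 = integer(), truth = character())
  } else {
    nf <- lengths(strsplit(body, "\t", fixed = TRUE))
    if (any(bad <- !(nf %in% c(9L, 10L)))) {
      ln <- which(bad)[1L]
      stop(sprintf("malformed .pairs line %d: expected 9 or 10 fields, got %d",
                   if (length(hdr)) ln + max(hdr) else ln, nf[which(bad)[1L]]))
    }
    tab <- data.table::fread(text = body, header = FALSE, sep = "\t")
    data.table::setnames(tab, cols[seq_len(ncol(tab))])
    tab[, `:=`(pos1 = as.numeric(pos1), pos2 = as.numeric(pos2),
               frag1 = as.integer(frag1), frag2 = as.integer(frag2))]
  }
  data.table::setattr(tab, "pairs_header", header)
  data.table::setattr(tab, "class", c("ditag_table", "data.table", "data.frame"))
  tab[]
}

#' @rdname read_pairs
#' @export
write_pairs <- function(table, path) {
  header <- attr(table, "pairs_header")
  cols <- intersect(c("readID", "chrom1", "pos1", "strand1", "chrom2", "pos2",
                      "strand2", "frag1", "frag2", "truth"), names(table))
  if (is.null(header))
    header <- c("## pairs-like dialect, 0-based coordinates",
                paste0("#columns: ", paste(cols, collapse = " ")))
  writeLines(header, path)
  if (nrow(table))
    data.table::fwrite(table[, cols, with = FALSE], path, sep = "\t",
                       col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Classify di-tags and summarize a library
#'
#' Resolves both ends of each di-tag against a fragment map and assigns each
#' mapped record exactly one class label, in priority order:
#'
#' 1. `same_fragment` — both ends on one fragment (self-circle/dangling end);
#' 2. `re_ligation` — ends on genomically adjacent fragments with inward
#'    orientation (the re-joined native cut site);
#' 3. `duplicate` — identical (canonically ordered) coordinate/strand tuple
#'    as an earlier record;
#' 4. `valid` — everything else.
#'
#' Locality (`cis`, `trans`, or cross-species `hybrid`) is assigned on
#' unique records, i.e. valid non-duplicates. Ends whose chromosome is not
#' in the map are counted as unmapped and excluded. The summary mirrors the
#' usual Hi-C pipeline report: `percent_re_ligation` is relative to mapped
#' di-tags, the locality percentages to unique di-tags (so cis + trans +
#' hybrid = 100 up to rounding).
#'
#' @param table A `ditag_table` (e.g. from [simulate_ditags()] or
#'   [read_pairs()]).
#' @param maps A `fragment_map`, list of per-species maps, or pooled map with
#'   chromosome names matching the table.
#' @return A list with `table` (input plus `class` and `locality` columns)
#'   and `summary` (one-row data.table: total, mapped, unmapped,
#'   n_same_fragment, n_re_ligation, n_duplicate, unique, percent_re_ligation,
#'   percent_cis, percent_trans, percent_hybrid).
#' @export
classify_ditags <- function(table, maps) {
  map <- if (inherits(maps, "fragment_map")) maps else pool_fragment_maps(maps)
  if (nrow(table) && !any(table$chrom1 %in% unique(map$chrom)) &&
      inherits(maps, "fragment_map"))
    map <- pool_fragment_maps(maps)  # table uses species-prefixed names
  tab <- data.table::copy(data.table::as.data.table(table))
  known <- unique(map$chrom)
  mapped <- tab$chrom1 %in% known & tab$chrom2 %in% known
  tab[, mapped := mapped]

  # canonical end order: (chrom, pos) ascending, so duplicates are
  # orientation-invariant
  swap <- tab$chrom1 > tab$chrom2 |
    (tab$chrom1 == tab$chrom2 & tab$pos1 > tab$pos2)
  for (cc in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                  c("strand1", "strand2"), c("frag1", "frag2"),
                  c("species1", "species2"))) {
    if (all(cc %in% names(tab))) {
      tmp <- tab[[cc[1]]][swap]
      data.table::set(tab, which(swap), cc[1], tab[[cc[2]]][swap])
      data.table::set(tab, which(swap), cc[2], tmp)
    }
  }

  sp_of <- map[, .(chrom, species)][!duplicated(chrom)]
  tab[, species1 := sp_of$species[match(chrom1, sp_of$chrom)]]
  tab[, species2 := sp_of$species[match(chrom2, sp_of$chrom)]]

  same_frag <- tab$mapped & tab$chrom1 == tab$chrom2 & tab$frag1 == tab$frag2
  # adjacent fragments, inward-facing (+ on the left end, - on the right):
  # the signature of re-ligated native cut sites
  adj <- tab$mapped & tab$chrom1 == tab$chrom2 &
    abs(tab$frag2 - tab$frag1) == 1L
  relig <- adj & !same_frag & tab$strand1 == "+" & tab$strand2 == "-"

  key <- paste(tab$chrom1, tab$pos1, tab$strand1,
               tab$chrom2, tab$pos2, tab$strand2)
  dup <- tab$mapped & duplicated(key) & !same_frag & !relig

  cls <- rep(NA_character_, nrow(tab))
  cls[tab$mapped] <- "valid"
  cls[dup] <- "duplicate"
  cls[relig] <- "re_ligation"
  cls[same_frag] <- "same_fragment"
  tab[, class := cls]

  loc <- rep(NA_character_, nrow(tab))
  uniq <- !is.na(cls) & cls == "valid"
  loc[uniq & tab$species1 != tab$species2] <- "hybrid"
  loc[uniq & tab$species1 == tab$species2 & tab$chrom1 != tab$chrom2] <- "trans"
  loc[uniq & tab$chrom1 == tab$chrom2] <- "cis"
  tab[, locality := loc]

  n_mapped <- sum(tab$mapped)
  n_uniq <- sum(uniq)
  pct <- function(x, d) if (d > 0) 100 * x / d else NA_real_
  summ <- data.table::data.table(
    total = nrow(tab), mapped = n_mapped, unmapped = nrow(tab) - n_mapped,
    n_same_fragment = sum(cls == "same_fragment", na.rm = TRUE),
    n_re_ligation = sum(cls == "re_ligation", na.rm = TRUE),
    n_duplicate = sum(cls == "duplicate", na.rm = TRUE),
    unique = n_uniq,
    percent_re_ligation = pct(sum(cls == "re_ligation", na.rm = TRUE), n_mapped),
    percent_cis = pct(sum(loc == "cis", na.rm = TRUE), n_uniq),
    percent_trans = pct(sum(loc == "trans", na.rm = TRUE), n_uniq),
    percent_hybrid = pct(sum(loc == "hybrid", na.rm = TRUE), n_uniq))

  data.table::setattr(tab, "chromosome_lengths",
                      attr(map, "chromosome_lengths"))
  data.table::setattr(tab, "class", c("ditag_table", "data.table", "data.frame"))
  list(table = tab[], summary = summ)
}

#' Paired test on per-replicate category-ratio differences
#'
#' One-sample two-sided t-test that the mean of paired differences of a
#' di-tag category ratio (e.g. percent re-ligation between matched library
#' preparations) is zero.
#'
#' @param deltas Numeric vector of paired differences (length >= 2).
#' @return List with `statistic`, `df`, `p_value`, `mean`, and `degenerate`
#'   (TRUE when the differences have zero variance, where the t statistic is
#'   undefined; then `statistic` is 0 or +/-Inf and `p_value` 1 or 0).
#' @export
paired_category_test <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 2L) stop("need at least 2 paired differences")
  m <- mean(deltas)
  if (stats::sd(deltas) == 0) {
    return(list(statistic = if (m == 0) 0 else sign(m) * Inf,
                df = length(deltas) - 1L,
                p_value = if (m == 0) 1 else 0,
                mean = m, degenerate = TRUE))
  }
  tt <- stats::t.test(deltas, mu = 0, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = m, degenerate = FALSE)
}
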