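## Interval containers and file I/O.
##
## Internal coordinates are 0-based half-open throughout (the native
## bedGraph/BED convention). Prose coordinates like "chr1:1-10" (1-based
## inclusive) convert as [a, b] -> [a - 1, b).

# ---- constructors -----------------------------------------------------------

#' Coverage track for one sample
#'
#' A sample's per-base read depth as sorted, non-overlapping valued
#' intervals (the in-memory form of a bedGraph).
#'
#' @param sample_id Sample identifier.
#' @param gr A [GenomicRanges::GRanges] with a numeric `score` column
#'   (depth per interval). Intervals must not overlap within a chromosome
#'   and scores must be non-negative; zero-depth intervals may be omitted.
#' @return An object of class `CoverageTrack`: a list with elements
#'   `sample_id` and `gr` (sorted).
#' @export
coverage_track <- function(sample_id, gr) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, is(gr, "GRanges"))
  if (is.null(gr$score)) {
    if (length(gr)) stop("coverage track needs a 'score' column")
    gr$score <- numeric(0)
  }
  if (any(gr$score < 0)) stop("coverage depth must be non-negative")
  seqlevels(gr) <- sort(seqlevels(gr))
  gr <- sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1L) {
    same <- as.character(seqnames(gr))[-length(gr)] ==
      as.character(seqnames(gr))[-1L]
    if (any(same & end(gr)[-length(gr)] > start(gr)[-1L]))
      stop("overlapping intervals in coverage track '", sample_id, "'")
  }
  structure(list(sample_id = sample_id, gr = gr), class = "CoverageTrack")
}

#' Binding-site set for one RBP
#'
#' @param rbp RBP symbol.
#' @param cell_line Label, conventionally one of `"lineA"`, `"lineB"`,
#'   `"merged"` (arbitrary labels are accepted).
#' @param gr A stranded [GenomicRanges::GRanges] (`+`/`-` only).
#' @return An object of class `BindingSiteSet`.
#' @export
binding_site_set <- function(rbp, cell_line, gr) {
  stopifnot(is.character(rbp), length(rbp) == 1L,
            is.character(cell_line), length(cell_line) == 1L,
            is(gr, "GRanges"))
  if (length(gr) && !all(as.character(strand(gr)) %in% c("+", "-")))
    stop("binding sites must be stranded (+/-)")
  seqlevels(gr) <- sort(seqlevels(gr))
  gr <- sort(gr, ignore.strand = TRUE)
  structure(list(rbp = rbp, cell_line = cell_line, gr = gr),
            class = "BindingSiteSet")
}

#' Gene/biotype annotation set
#'
#' A single genomic region may carry multiple records with different
#' biotypes (e.g. a region annotated both as pseudogene and unprocessed
#' pseudogene); each record is kept.
#'
#' @param gr A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `biotype`, `gene_name`.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  need <- c("gene_id", "biotype", "gene_name")
  miss <- setdiff(need, names(mcols(gr)))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  seqlevels(gr) <- sort(seqlevels(gr))
  structure(list(gr = sort(gr, ignore.strand = TRUE)), class = "AnnotationSet")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack '", x$sample_id, "': ", length(x$gr), " intervals on ",
      length(seqlevels(x$gr)), " sequence(s)\n", sep = "")
  invisible(x)
}

#' @export
print.BindingSiteSet <- function(x, ...) {
  cat("BindingSiteSet ", x$rbp, " [", x$cell_line, "]: ", length(x$gr),
      " sites\n", sep = "")
  invisible(x)
}

# ---- line-oriented parsing --------------------------------------------------

# gzfile() reads plain and gzip files alike
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

is_header_line <- function(x) {
  grepl("^(track|browser)\\b", x) | grepl("^#", x) | !nzchar(trimws(x))
}

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

# ---- bedGraph ---------------------------------------------------------------

#' Read a bedGraph coverage file
#'
#' Reads 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a [coverage_track()]. `track`/`browser` header and comment lines
#' are skipped; plain and gzip files are both accepted. Malformed lines
#' raise an error naming the line number; overlapping intervals within the
#' file raise a validation error.
#'
#' @param path Path to a bedGraph file (optionally gzipped).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extensions.
#' @return A `CoverageTrack`.
#' @export
read_coverage <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.(bedgraph|bedGraph|bg|txt)(\\.gz)?$", "",
                                  basename(path))
  lines <- read_text_lines(path)
  keep <- !is_header_line(lines)
  if (!any(keep))
    return(coverage_track(sample_id, GRanges()))
  lineno <- which(keep)
  fields <- split_fields(lines[keep])
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", lineno[which(nf < 4L)[1L]], " in ", path,
         ": expected 4 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path,
         ": non-numeric coordinate or value")
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]], " in ", path,
         ": need start >= 0 and end > start")
  if (any(value < 0))
    stop("malformed bedGraph line ", lineno[which(value < 0)[1L]], " in ",
         path, ": negative depth")
  gr <- GRanges(chrom, IRanges(start + 1L, end), score = value)
  coverage_track(sample_id, gr)
}

#' Write a coverage track as bedGraph
#'
#' Output is sorted by (chrom, start); a `.gz` extension triggers gzip
#' compression. Round-trips through [read_coverage()] exactly.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  gr <- sort(track$gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), value = gr$score)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---- BED6 / narrowPeak ------------------------------------------------------

#' Read binding sites from a BED6/narrowPeak file
#'
#' Requires at least 6 columns with the strand in column 6; extra
#' narrowPeak columns are ignored. Sites are returned sorted. Unknown
#' strand symbols (anything but `+`/`-`) are an error.
#'
#' @param path Path to a BED6/narrowPeak file (optionally gzipped).
#' @param rbp RBP symbol for the set.
#' @param cell_line Cell-line label.
#' @return A `BindingSiteSet`.
#' @export
read_sites <- function(path, rbp, cell_line) {
  lines <- read_text_lines(path)
  keep <- !is_header_line(lines)
  if (!any(keep))
    return(binding_site_set(rbp, cell_line, GRanges()))
  lineno <- which(keep)
  fields <- split_fields(lines[keep])
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("line ", lineno[which(nf < 6L)[1L]], " in ", path,
         ": BED6/narrowPeak needs >= 6 columns (strand missing?)")
  chrom  <- vapply(fields, `[`, "", 1L)
  start  <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end    <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  name   <- vapply(fields, `[`, "", 4L)
  strand <- vapply(fields, `[`, "", 6L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", lineno[bad[1L]], " in ", path, ": non-numeric coordinates")
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("line ", lineno[bad[1L]], " in ", path,
         ": need start >= 0 and end > start")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("line ", lineno[bad[1L]], " in ", path, ": unknown strand symbol '",
         strand[bad[1L]], "'")
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand, name = name)
  binding_site_set(rbp, cell_line, gr)
}

#' Write a binding-site set (or any stranded GRanges) as BED6
#'
#' @param x A `BindingSiteSet` or `GRanges`.
#' @param path Output path (`.gz` compresses).
#' @param names Optional name column; defaults to the `name` metadata
#'   column or `"."`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(x, path, names = NULL) {
  gr <- if (is(x, "BindingSiteSet")) x$gr else x
  gr <- sort(gr, ignore.strand = TRUE)
  nm <- names %||% (mcols(gr)$name %||% rep(".", length(gr)))
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), name = nm, score = 0L,
                   strand = as.character(strand(gr)))
  df$strand[df$strand == "*"] <- "."
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED-like annotation file
#'
#' Expects tab/space separated columns chrom, start, end, gene_id, biotype,
#' gene_name and optionally strand (column 7). Multiple records may share
#' coordinates with different biotypes.
#'
#' @param path Path (optionally gzipped).
#' @return An `AnnotationSet`.
#' @export
read_annotation <- function(path) {
  lines <- read_text_lines(path)
  keep <- !is_header_line(lines)
  if (!any(keep)) return(annotation_set(GRanges(gene_id = character(),
                                                biotype = character(),
                                                gene_name = character())))
  fields <- split_fields(lines[keep])
  if (any(lengths(fields) < 6L))
    stop("annotation lines need >= 6 columns ",
         "(chrom start end gene_id biotype gene_name)")
  strand <- vapply(fields, function(f) if (length(f) >= 7L) f[7L] else "*", "")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(vapply(fields, `[`, "", 1L),
                IRanges(as.numeric(vapply(fields, `[`, "", 2L)) + 1L,
                        as.numeric(vapply(fields, `[`, "", 3L))),
                strand = strand,
                gene_id = vapply(fields, `[`, "", 4L),
                biotype = vapply(fields, `[`, "", 5L),
                gene_name = vapply(fields, `[`, "", 6L))
  annotation_set(gr)
}

# ---- interval algebra -------------------------------------------------------

#' Strand-aware union of two cell lines' binding sites
#'
#' Same-strand overlapping or book-ended intervals are coalesced;
#' opposite-strand overlaps are kept separate. The operation is idempotent
#' and commutative.
#'
#' @param a,b `BindingSiteSet`s for the same RBP.
#' @return A `BindingSiteSet` with `cell_line = "merged"`.
#' @export
merge_cross_cell_line <- function(a, b) {
  stopifnot(is(a, "BindingSiteSet"), is(b, "BindingSiteSet"))
  if (!identical(a$rbp, b$rbp))
    stop("cannot merge sites of different RBPs: ", a$rbp, " vs ", b$rbp)
  gr <- reduce(c(granges(a$gr), granges(b$gr)))  # strand-aware, book-ended coalesced
  binding_site_set(a$rbp, "merged", gr)
}

#' Atomic partition of a union of binding-site sets
#'
#' Splits the union of all sites into maximal intervals over which the set
#' of covering RBPs is constant ("atoms"). For example, RBP A binding
#' chr1:1-10 and RBP B binding chr1:5-15 (1-based inclusive) partition into
#' three atoms chr1:1-5, chr1:6-10, chr1:11-15 with memberships {A},
#' {A,B}, {B}. Strand is ignored for the partition (sample-centric
#' intersections are unstranded).
#'
#' @param sets Non-empty list of `BindingSiteSet`s.
#' @return A list with `atoms` (sorted, disjoint `GRanges` whose union
#'   equals the union of the inputs) and `members` (list of member RBP
#'   symbol vectors, sorted, one per atom).
#' @export
partition_union <- function(sets) {
  stopifnot(is.list(sets), length(sets) > 0L)
  grl <- lapply(sets, function(s) {
    stopifnot(is(s, "BindingSiteSet"))
    g <- granges(s$gr)
    mcols(g)$rbp <- s$rbp
    g
  })
  all_gr <- do.call(c, unname(grl))
  if (!length(all_gr)) return(list(atoms = GRanges(), members = list()))
  atoms <- disjoin(all_gr, ignore.strand = TRUE)
  atoms <- sort(atoms, ignore.strand = TRUE)
  hits <- findOverlaps(atoms, all_gr, ignore.strand = TRUE)
  members <- rep(list(character()), length(atoms))
  got <- split(all_gr$rbp[subjectHits(hits)], queryHits(hits))
  idx <- as.integer(names(got))
  members[idx] <- lapply(got, function(x) sort(unique(x)))
  # disjoin() also splits at boundaries internal to one RBP's overlapping
  # sites; coalesce book-ended atoms whose memberships are identical so
  # atoms are maximal
  if (length(atoms) > 1L) {
    key <- vapply(members, paste, "", collapse = ";")
    n <- length(atoms)
    joinable <- as.character(seqnames(atoms))[-n] ==
      as.character(seqnames(atoms))[-1L] &
      end(atoms)[-n] + 1L == start(atoms)[-1L] &
      key[-n] == key[-1L]
    run <- cumsum(c(TRUE, !joinable))
    starts <- tapply(start(atoms), run, min)
    ends <- tapply(end(atoms), run, max)
    first <- which(!duplicated(run))
    atoms <- GRanges(as.character(seqnames(atoms))[first],
                     IRanges(as.vector(starts), as.vector(ends)))
    members <- members[first]
  }
  list(atoms = atoms, members = members)
}

#' Assemble the region-set file library across cell lines
#'
#' Given per-cell-line binding-site sets, returns the full library used for
#' intersections: every cell-line-specific set plus one strand-aware merged
#' set for each RBP present in more than one cell line. With 103 + 120
#' cell-line sets sharing 73 RBPs this yields 296 region sets.
#'
#' @param sets List of `BindingSiteSet`s (mixed cell lines).
#' @return Named list of `BindingSiteSet`s (names `rbp.cell_line`).
#' @export
site_library <- function(sets) {
  stopifnot(all(vapply(sets, is, TRUE, "BindingSiteSet")))
  rbps <- vapply(sets, `[[`, "", "rbp")
  out <- sets
  names(out) <- paste(rbps, vapply(sets, `[[`, "", "cell_line"), sep = ".")
  for (r in unique(rbps[duplicated(rbps)])) {
    own <- sets[rbps == r]
    merged <- Reduce(merge_cross_cell_line, own)
    out[[paste(r, "merged", sep = ".")]] <- merged
  }
  out
}

#' Write atomic regions as BED, encoding memberships in the name column
#'
#' @param partition Result of [partition_union()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atoms <- function(partition, path) {
  gr <- partition$atoms
  nm <- vapply(partition$members, paste, "", collapse = ";")
  write_sites(gr, path, names = nm)
}
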