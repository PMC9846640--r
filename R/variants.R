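#' Variant normalization for syntenic-caller VCF output
#'
#' Whole-genome syntenic variant callers emit a VCF-like dialect that breaks
#' strict VCF semantics: the same variant can be reported once per overlapping
#' syntenic block (duplicates), long insertions can be split across several
#' records sharing an anchor position (fragments), and nonstandard INFO keys
#' (`ChrB`, `Parent`, `DupType`, `modified`) carry alignment provenance.
#' The functions in this file parse that dialect into a `variant_set`,
#' deduplicate it, merge fragmented insertions, classify events by the 50 bp
#' small-indel/SV rule, and split by variant type.
#'
#' @name variant-normalization
NULL

.VTYPES <- c("SNP", "INS", "DEL", "INV", "TRANS")
.SIZE_CLASSES <- c("SNP", "SMALL_INDEL", "SV", "OTHER")
.SV_MIN_BP <- 50L

.vs_columns <- c("chrom", "pos", "id", "ref", "alt", "vtype", "size",
                 "size_class", "fragments", "chrb", "parent", "duptype",
                 "modified")

#' Construct a variant set
#'
#' A `variant_set` is a data frame of normalized variant records for a single
#' genotype, ordered by `(chrom, pos)`, with the caller's INFO keys preserved
#' as columns. Coordinates are 1-based inclusive (VCF convention).
#'
#' @param records data frame with at least columns `chrom`, `pos`, `ref`,
#'   `alt`, `vtype`; missing bookkeeping columns are filled with defaults.
#' @param genotype genotype label the records belong to.
#' @param provenance character vector recording source path and the
#'   normalization steps already applied.
#' @return An object of class `variant_set` (a data frame).
#' @export
variant_set <- function(records, genotype, provenance = character()) {
  stopifnot(is.data.frame(records))
  need <- c("chrom", "pos", "ref", "alt", "vtype")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("missing variant columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  if (!"id" %in% names(records)) records$id <- rep(".", n)
  if (!"size" %in% names(records))
    records$size <- variant_size(records$vtype, records$ref, records$alt)
  if (!"size_class" %in% names(records))
    records$size_class <- classify_size(records$vtype, records$size)
  if (!"fragments" %in% names(records)) records$fragments <- rep(1L, n)
  for (k in c("chrb", "parent", "duptype", "modified"))
    if (!k %in% names(records)) records[[k]] <- rep(NA_character_, n)
  records <- records[.vs_columns]
  records$pos <- as.integer(records$pos)
  if (n > 0L && any(records$pos < 1L))
    stop("variant positions must be >= 1 (1-based VCF convention)")
  bad <- records$vtype %in% c("SNP", "INS", "DEL") &
    (!grepl("^[ACGTN]+$", records$ref) | !grepl("^[ACGTN]+$", records$alt))
  if (any(bad))
    stop("REF/ALT must be nonempty strings over {A,C,G,T,N} for SNP/INS/DEL")
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            genotype = as.character(genotype),
            provenance = provenance,
            class = c("variant_set", "data.frame"))
}

.vs_rebuild <- function(records, template, step) {
  variant_set(records, attr(template, "genotype"),
              c(attr(template, "provenance"), step))
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records, genotype '%s'\n",
              nrow(x), attr(x, "genotype")))
  if (nrow(x) > 0L) {
    tab <- table(factor(x$vtype, levels = .VTYPES))
    cat("  by type:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  if (length(attr(x, "provenance")) > 0L)
    cat("  provenance:", paste(attr(x, "provenance"), collapse = " -> "), "\n")
  invisible(x)
}

#' Event size of a variant record
#'
#' SNPs have size 0; insertions and deletions use the anchored-allele length
#' difference `|nchar(alt) - nchar(ref)|`; inversions and translocations use
#' the span recorded by the caller (passed via `span`).
#'
#' @param vtype character vector of variant types.
#' @param ref,alt allele strings.
#' @param span optional integer span for INV/TRANS records (0 when unknown).
#' @return Integer vector of sizes in bp.
#' @export
variant_size <- function(vtype, ref, alt, span = 0L) {
  span <- rep_len(as.integer(span), length(vtype))
  out <- integer(length(vtype))
  indel <- vtype %in% c("INS", "DEL")
  out[indel] <- abs(nchar(alt[indel]) - nchar(ref[indel]))
  big <- vtype %in% c("INV", "TRANS")
  out[big] <- span[big]
  out
}

#' Classify a variant by the 50 bp size rule
#'
#' SNPs map to class `SNP`; insertions/deletions smaller than 50 bp are
#' `SMALL_INDEL` and those of 50 bp or more are `SV`; inversions,
#' translocations and unrecognized types are `OTHER` and are excluded from
#' downstream occupancy analysis.
#'
#' @param vtype character vector of variant types.
#' @param size integer event sizes in bp (must be non-negative).
#' @return Character vector over `SNP`, `SMALL_INDEL`, `SV`, `OTHER`.
#' @examples
#' classify_size(c("DEL", "INS", "SNP"), c(49, 50, 0))
#' @export
classify_size <- function(vtype, size) {
  size <- as.integer(size)
  if (any(is.na(size)) || any(size < 0L))
    stop("variant size must be a non-negative integer")
  if (length(size) == 1L) size <- rep_len(size, length(vtype))
  out <- rep("OTHER", length(vtype))
  out[vtype == "SNP"] <- "SNP"
  indel <- vtype %in% c("INS", "DEL")
  out[indel & size < .SV_MIN_BP] <- "SMALL_INDEL"
  out[indel & size >= .SV_MIN_BP] <- "SV"
  out
}

.parse_info <- function(info) {
  # INFO is ;-separated key=value (flags allowed); returns a named list of
  # character vectors aligned with `info`.
  keys <- c(chrb = "ChrB", parent = "Parent", duptype = "DupType",
            modified = "modified", end = "END")
  out <- lapply(keys, function(k) {
    m <- regmatches(info, regexpr(paste0("(^|;)", k, "=[^;]*"), info))
    has <- grepl(paste0("(^|;)", k, "="), info)
    val <- rep(NA_character_, length(info))
    val[has] <- sub(paste0("^;?", k, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", k, "=[^;]*"),
                                             info)))
    val
  })
  names(out) <- names(keys)
  out
}

#' Parse a syntenic-caller VCF file into a variant set
#'
#' Reads the caller's VCF-like dialect (plain or gzip/bgzip text). Every data
#' line yields exactly one record; no deduplication or fragment merging is
#' performed here. Variant types are derived from the alleles: symbolic ALTs
#' `<INV>`/`<TRANS>` (other symbolic codes are flagged `OTHER` with a
#' warning), otherwise single-base REF and ALT is a SNP, a longer ALT an
#' insertion and a longer REF a deletion.
#'
#' @param path path to the VCF file.
#' @param genotype genotype label to attach.
#' @return A [variant_set()] in file order of the retained columns, sorted by
#'   `(chrom, pos)`.
#' @export
read_syri_vcf <- function(path, genotype) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body_idx) == 0L)
    return(variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  vtype = character()),
                       genotype, provenance = path))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) >= 8L
  if (!all(ncol_ok))
    stop(sprintf("malformed VCF line %d: expected >= 8 tab-separated columns",
                 body_idx[which(!ncol_ok)[1L]]))
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(1L); pos <- as.integer(get(2L)); id <- get(3L)
  ref <- toupper(get(4L)); alt <- toupper(get(5L)); info <- get(8L)
  symbolic <- startsWith(alt, "<")
  code <- toupper(sub("^<([^>]*)>$", "\\1", alt))
  vtype <- character(length(alt))
  vtype[symbolic] <- ifelse(code[symbolic] %in% c("INV", "TRANS"),
                            code[symbolic], "OTHER")
  plain <- !symbolic
  nr <- nchar(ref); na <- nchar(alt)
  vtype[plain & nr == 1L & na == 1L] <- "SNP"
  vtype[plain & na > nr] <- "INS"
  vtype[plain & na < nr] <- "DEL"
  vtype[plain & nr == na & nr > 1L] <- "OTHER"
  if (any(vtype == "OTHER")) {
    warning(sprintf("%d record(s) with unrecognized variant type flagged OTHER",
                    sum(vtype == "OTHER")))
  }
  ex <- .parse_info(info)
  span <- rep(0L, length(pos))
  has_end <- !is.na(ex$end)
  span[has_end] <- pmax(0L, as.integer(ex$end[has_end]) - pos[has_end] + 1L)
  rec <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
                    vtype = vtype,
                    size = variant_size(vtype, ref, alt, span),
                    chrb = ex$chrb, parent = ex$parent, duptype = ex$duptype,
                    modified = ex$modified,
                    stringsAsFactors = FALSE)
  # symbolic records carry placeholder alleles; keep them verbatim
  variant_set(rec, genotype, provenance = path)
}

#' Canonical identity key of each record
#'
#' The identity used for deduplication and cross-genotype merging:
#' `(chrom, pos, vtype, ref, alt)`. INFO fields are deliberately excluded so
#' that block-level duplicates differing only in provenance collapse.
#'
#' @param vs a `variant_set` or compatible data frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(vs) {
  paste(vs$chrom, vs$pos, vs$vtype, vs$ref, vs$alt, sep = ":")
}

#' Remove duplicated variant records
#'
#' Keeps the first occurrence of each identity key (see [variant_key()]);
#' idempotent.
#'
#' @param vs a [variant_set()].
#' @return Deduplicated `variant_set`, sorted by `(chrom, pos)`.
#' @export
deduplicate_variants <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  keep <- !duplicated(variant_key(vs))
  .vs_rebuild(as.data.frame(vs)[keep, , drop = FALSE], vs, "deduplicate")
}

.insert_part <- function(ref, alt) substring(alt, nchar(ref) + 1L)

#' Merge fragmented insertion records
#'
#' Syntenic callers can split one long insertion into several INS records
#' whose anchor positions coincide or nearly coincide. Insertions on the same
#' chromosome whose consecutive anchor positions differ by at most `gap_tol`
#' bp are combined into a single record: the merged position is the minimum
#' anchor, the merged ALT is the first fragment's anchored allele followed by
#' the inserted parts of the remaining fragments in ascending anchor order
#' (ties broken by input order), and the `fragments` column records how many
#' records were combined. Non-INS records pass through untouched. Total
#' inserted length is conserved.
#'
#' @param vs a deduplicated [variant_set()].
#' @param gap_tol non-negative anchor distance (bp) within which consecutive
#'   insertion fragments merge; the default 0 merges identical anchors only.
#' @return `variant_set` with fragment clusters collapsed.
#' @export
merge_fragmented_insertions <- function(vs, gap_tol = 0L) {
  stopifnot(inherits(vs, "variant_set"))
  if (length(gap_tol) != 1L || is.na(gap_tol) || gap_tol < 0)
    stop("gap_tol must be a single non-negative integer")
  gap_tol <- as.integer(gap_tol)
  df <- as.data.frame(vs)
  ins <- df[df$vtype == "INS", , drop = FALSE]
  rest <- df[df$vtype != "INS", , drop = FALSE]
  if (nrow(ins) <= 1L)
    return(.vs_rebuild(df, vs, sprintf("merge_fragments(gap_tol=%d)", gap_tol)))
  # stable sort by (chrom, pos): ties keep input order
  ins <- ins[order(ins$chrom, ins$pos), , drop = FALSE]
  new_chrom <- c(TRUE, ins$chrom[-1L] != ins$chrom[-nrow(ins)])
  gap <- c(0L, diff(ins$pos))
  cluster <- cumsum(new_chrom | gap > gap_tol)
  merged <- lapply(split(seq_len(nrow(ins)), cluster), function(idx) {
    first <- ins[idx[1L], , drop = FALSE]
    if (length(idx) > 1L) {
      tail_ins <- .insert_part(ins$ref[idx[-1L]], ins$alt[idx[-1L]])
      first$alt <- paste0(first$alt, paste(tail_ins, collapse = ""))
      first$fragments <- sum(ins$fragments[idx])
      first$id <- ins$id[idx[1L]]
    }
    first
  })
  out <- rbind(do.call(rbind, merged), rest)
  out$size <- variant_size(out$vtype, out$ref, out$alt, out$size)
  out$size_class <- classify_size(out$vtype, out$size)
  .vs_rebuild(out, vs, sprintf("merge_fragments(gap_tol=%d)", gap_tol))
}

#' Normalize a variant set
#'
#' Convenience wrapper: deduplicate, then merge fragmented insertions.
#'
#' @inheritParams merge_fragmented_insertions
#' @return Normalized `variant_set`.
#' @export
normalize_variants <- function(vs, gap_tol = 0L) {
  merge_fragmented_insertions(deduplicate_variants(vs), gap_tol)
}

#' Split a variant set by variant type
#'
#' @param vs a [variant_set()].
#' @return Named list of `variant_set`s, one per type present (in the
#'   canonical order SNP, INS, DEL, INV, TRANS); the union of the outputs is
#'   the input.
#' @export
split_by_type <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  df <- as.data.frame(vs)
  present <- .VTYPES[.VTYPES %in% df$vtype]
  out <- lapply(present, function(tp) {
    .vs_rebuild(df[df$vtype == tp, , drop = FALSE], vs,
                sprintf("split(%s)", tp))
  })
  names(out) <- present
  out
}

#' Write a variant set as standards-conformant VCF
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  df <- as.data.frame(vs)
  info <- vapply(seq_len(nrow(df)), function(i) {
    kv <- c(ChrB = df$chrb[i], Parent = df$parent[i], DupType = df$duptype[i],
            modified = df$modified[i])
    kv <- kv[!is.na(kv)]
    if (df$vtype[i] %in% c("INV", "TRANS") && df$size[i] > 0L)
      kv <- c(END = df$pos[i] + df$size[i] - 1L, kv)
    if (df$fragments[i] > 1L) kv <- c(kv, Fragments = df$fragments[i])
    if (length(kv) == 0L) "." else
      paste(sprintf("%s=%s", names(kv), kv), collapse = ";")
  }, "")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=pansorghum;genotype=%s", attr(vs, "genotype")),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(df) == 0L) character() else
    paste(df$chrom, df$pos, df$id, df$ref, df$alt, ".", "PASS", info,
          sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
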