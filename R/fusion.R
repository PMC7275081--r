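#' Candidate fusions from SV calls
#'
#' An SV call is a candidate fusion when its two breakends fall inside
#' two different genes. Each (call, gene-at-end1, gene-at-end2)
#' combination with distinct genes yields one candidate, so breakends in
#' overlapping genes produce one candidate per gene pair. Calls with an
#' intergenic end are excluded from candidacy — they remain available in
#' the SV VCF, where rearrangements such as enhancer hijacking events
#' with a breakpoint outside any gene body can still be inspected.
#'
#' The gene query point for a breakend is its retained base: `pos - 1`
#' for side L, `pos` for side R.
#'
#' @param calls `sv_calls` data.frame
#' @param models `GeneModelSet`
#' @return data.frame with columns `call_idx`, `gene1`, `gene2` (gene IDs
#'   at end1/end2)
#' @export
candidate_fusions <- function(calls, models) {
  out <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    g1 <- genes_at(models, cl$chrom1, retained_base(cl$pos1, cl$side1))
    g2 <- genes_at(models, cl$chrom2, retained_base(cl$pos2, cl$side2))
    for (a in g1) for (b in g2) {
      if (a$id == b$id) next
      out[[length(out) + 1L]] <- data.frame(
        call_idx = i, gene1 = a$id, gene2 = b$id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(call_idx = integer(), gene1 = character(),
                      gene2 = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

retained_base <- function(pos, side) {
  if (side == "L") pos - 1L else pos
}

#' Is a gene a valid 5' (or 3') fusion partner at a breakend?
#'
#' The continuous-transcript rule: the 5' partner must retain its
#' transcript-upstream flank at the junction — retained side L for a '+'
#' gene, R for a '-' gene — and the 3' partner its transcript-downstream
#' flank (R for '+', L for '-'). Only junctions pairing one
#' upstream-retained and one downstream-retained gene can be transcribed
#' through on a single strand.
#'
#' @param side retained side at the breakend, "L" or "R"
#' @param strand gene strand, "+" or "-"
#' @return logical
#' @export
valid_5prime <- function(side, strand) {
  (side == "L" & strand == "+") | (side == "R" & strand == "-")
}

#' @rdname valid_5prime
#' @export
valid_3prime <- function(side, strand) {
  (side == "R" & strand == "+") | (side == "L" & strand == "-")
}

#' Orient a candidate fusion by the continuous-transcript rule
#'
#' Tries both role assignments (geneA 5' / geneB 3', and the swap); a
#' `FusionCall` is emitted per valid assignment and a candidate where
#' neither holds is rejected (e.g. two promoter-proximal halves joined
#' head-to-head). Rejection is a normal outcome, not an error.
#'
#' @param call one-row `sv_calls` data.frame
#' @param geneA,geneB `Gene` objects at end1 and end2 of the call
#' @return list of `FusionCall` objects (length 0-2), each a list with
#'   `gene5`, `gene3`, `chrom5`, `bp5`, `side5`, `chrom3`, `bp3`,
#'   `side3`, `support`, `support_reads`, `wide_ci`, `source_sv`
#' @export
orient_fusion <- function(call, geneA, geneB) {
  ends <- list(
    list(chrom = call$chrom1, pos = call$pos1, side = call$side1),
    list(chrom = call$chrom2, pos = call$pos2, side = call$side2))
  mk <- function(g5, e5, g3, e3) {
    structure(list(
      gene5 = g5, gene3 = g3,
      chrom5 = e5$chrom, bp5 = e5$pos, side5 = e5$side,
      chrom3 = e3$chrom, bp3 = e3$pos, side3 = e3$side,
      support = call$support, support_reads = call$support_reads[[1]],
      wide_ci = isTRUE(call$wide_ci), source_sv = call$id),
      class = "FusionCall")
  }
  out <- list()
  if (valid_5prime(ends[[1]]$side, geneA$strand) &&
      valid_3prime(ends[[2]]$side, geneB$strand))
    out <- c(out, list(mk(geneA, ends[[1]], geneB, ends[[2]])))
  if (valid_5prime(ends[[2]]$side, geneB$strand) &&
      valid_3prime(ends[[1]]$side, geneA$strand))
    out <- c(out, list(mk(geneB, ends[[2]], geneA, ends[[1]])))
  out
}

#' Compose the coding sequence of an oriented fusion
#'
#' `cds5_len` counts canonical-transcript CDS bases on the retained flank
#' of the 5' gene (transcript-5' of the breakpoint); `cds3_len` those on
#' the retained flank of the 3' gene (breakpoint through stop);
#' `fused_cds_len` is their sum. Flags:
#' \describe{
#'   \item{OUT_OF_FRAME}{both genes code and the fused CDS length is not
#'     a multiple of 3}
#'   \item{NO_CDS}{either gene has no coding transcript; CDS lengths
#'     report 0 for that gene}
#'   \item{PROMOTER_5}{the 5' gene codes but the breakpoint lies upstream
#'     of its CDS start (promoter-fusion-like; retained, not dropped)}
#' }
#'
#' @param fusion a `FusionCall` from [orient_fusion()]
#' @return the `FusionCall` with `cds5_len`, `cds3_len`,
#'   `fused_cds_len`, `locus5`, `locus3` and `flags` filled in
#' @export
compose_cds <- function(fusion) {
  g5 <- fusion$gene5; g3 <- fusion$gene3
  rb5 <- retained_base(fusion$bp5, fusion$side5)
  rb3 <- retained_base(fusion$bp3, fusion$side3)
  if (rb5 < g5$start || rb5 >= g5$end)
    stop("5' breakpoint outside span of gene ", g5$id)
  if (rb3 < g3$start || rb3 >= g3$end)
    stop("3' breakpoint outside span of gene ", g3$id)
  cds5 <- cds_flank_length(g5, fusion$bp5,
                           flank = if (fusion$side5 == "L") "left" else "right")
  cds3 <- cds_flank_length(g3, fusion$bp3,
                           flank = if (fusion$side3 == "L") "left" else "right")
  flags <- character(0)
  coding5 <- gene_cds_length(g5) > 0
  coding3 <- gene_cds_length(g3) > 0
  if (!coding5 || !coding3) flags <- c(flags, "NO_CDS")
  if (coding5 && coding3 && (cds5 + cds3) %% 3 != 0)
    flags <- c(flags, "OUT_OF_FRAME")
  if (coding5 && cds5 == 0) flags <- c(flags, "PROMOTER_5")
  if (fusion$wide_ci) flags <- c(flags, "WIDE_CI")
  fusion$cds5_len <- cds5
  fusion$cds3_len <- cds3
  fusion$fused_cds_len <- cds5 + cds3
  fusion$locus5 <- locate(g5, rb5)$label
  fusion$locus3 <- locate(g3, rb3)$label
  fusion$flags <- flags
  fusion
}

#' Link reciprocal fusion calls
#'
#' Two fusions are reciprocal iff they involve the same two genes with
#' the 5'/3' roles exchanged; both receive a `RECIPROCAL_OF:<id>` flag.
#' Breakpoints need not match: reciprocal products of a balanced
#' rearrangement are location-independent.
#'
#' @param fusions list of composed `FusionCall`s with `$id` assigned
#' @return the list, with flags updated
#' @export
link_reciprocals <- function(fusions) {
  n <- length(fusions)
  if (n < 2) return(fusions)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    fi <- fusions[[i]]; fj <- fusions[[j]]
    if (fi$gene5$id == fj$gene3$id && fi$gene3$id == fj$gene5$id) {
      fusions[[i]]$flags <- union(fusions[[i]]$flags,
                                  paste0("RECIPROCAL_OF:", fj$id))
      fusions[[j]]$flags <- union(fusions[[j]]$flags,
                                  paste0("RECIPROCAL_OF:", fi$id))
    }
  }
  fusions
}

#' Annotate chained SV calls
#'
#' Two calls are chained when they share at least one supporting read and
#' any two of their breakend positions (same chromosome) lie within
#' `max_gap`. Chains mark the components of complex events — e.g. a short
#' deletion and inversion adjacent to an interchromosomal fusion — whose
#' automatic single-call reconstruction is best-effort; the components
#' remain individually reported for manual inspection.
#'
#' @param calls `sv_calls` data.frame
#' @param max_gap maximum breakend distance (bases) for chaining
#' @return character vector (length `nrow(calls)`): comma-joined partner
#'   call IDs, or `NA` for unchained calls
#' @export
annotate_chains <- function(calls, max_gap = 1000) {
  n <- nrow(calls)
  partners <- vector("list", n)
  if (n >= 2) {
    endlist <- lapply(seq_len(n), function(i)
      data.frame(chrom = c(calls$chrom1[i], calls$chrom2[i]),
                 pos = c(calls$pos1[i], calls$pos2[i]),
                 stringsAsFactors = FALSE))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      share <- length(intersect(calls$support_reads[[i]],
                                calls$support_reads[[j]])) > 0
      if (!share) next
      near <- FALSE
      for (a in 1:2) for (b in 1:2) {
        if (endlist[[i]]$chrom[a] == endlist[[j]]$chrom[b] &&
            abs(endlist[[i]]$pos[a] - endlist[[j]]$pos[b]) <= max_gap)
          near <- TRUE
      }
      if (near) {
        partners[[i]] <- c(partners[[i]], calls$id[j])
        partners[[j]] <- c(partners[[j]], calls$id[i])
      }
    }
  }
  vapply(partners, function(p)
    if (is.null(p)) NA_character_ else paste(sort(unique(p)), collapse = ","),
    character(1))
}

#' Call fusion genes from clustered SVs
#'
#' Full annotation chain: candidate selection, orientation by the
#' continuous-transcript rule, CDS composition and flags, reciprocal
#' linking, chain annotation, and (when a reference is given)
#' breakpoint-spanning primer design on the junction sequence of the
#' derivative allele.
#'
#' @param calls `sv_calls` data.frame from [cluster_breakends()]
#' @param models `GeneModelSet`
#' @param reference optional [Biostrings::DNAStringSet] for primer design
#' @param primer_flank bases of retained sequence per side used to build
#'   the junction sequence for primer design
#' @return list of composed `FusionCall`s, each with an `$id` (FG1, ...)
#' @export
call_fusions <- function(calls, models, reference = NULL,
                         primer_flank = 600) {
  cands <- candidate_fusions(calls, models)
  chains <- annotate_chains(calls)
  fusions <- list()
  for (i in seq_len(nrow(cands))) {
    cl <- calls[cands$call_idx[i], ]
    oriented <- orient_fusion(cl, models$genes[[cands$gene1[i]]],
                              models$genes[[cands$gene2[i]]])
    for (fu in oriented) {
      fu <- compose_cds(fu)
      ch <- chains[cands$call_idx[i]]
      if (!is.na(ch)) fu$flags <- union(fu$flags, paste0("CHAIN:", ch))
      fusions[[length(fusions) + 1L]] <- fu
    }
  }
  for (i in seq_along(fusions)) fusions[[i]]$id <- paste0("FG", i)
  fusions <- link_reciprocals(fusions)
  if (!is.null(reference)) {
    for (i in seq_along(fusions)) {
      fu <- fusions[[i]]
      pr <- tryCatch({
        js <- junction_sequence(reference, fu, flank = primer_flank)
        design_primers(js$seq, js$junction_offset)
      }, error = function(e) NULL)
      if (is.null(pr)) {
        fusions[[i]]$flags <- union(fu$flags, "PRIMER_FAIL")
      } else {
        fusions[[i]]$primers <- pr
      }
    }
  }
  fusions
}

#' Junction sequence of the derivative allele around a fusion breakpoint
#'
#' Concatenates the retained flank of the 5' end (oriented so the
#' junction is at its right edge) and the retained flank of the 3' end
#' (junction at its left edge). Side L keeps reference orientation; side
#' R flanks are reverse-complemented as needed so the two retained pieces
#' abut exactly as in the derivative chromosome.
#'
#' @param reference [Biostrings::DNAStringSet]
#' @param fusion a `FusionCall`
#' @param flank bases per side
#' @return list with `seq` (character) and `junction_offset` (0-based
#'   offset of the junction within `seq`)
#' @export
junction_sequence <- function(reference, fusion, flank = 600) {
  left <- flank_sequence(reference, fusion$chrom5, fusion$bp5,
                         fusion$side5, flank, junction_edge = "right")
  right <- flank_sequence(reference, fusion$chrom3, fusion$bp3,
                          fusion$side3, flank, junction_edge = "left")
  list(seq = paste0(left, right), junction_offset = nchar(left))
}

flank_sequence <- function(reference, chrom, pos, side, flank,
                           junction_edge) {
  seq <- reference[[chrom]]
  len <- length(seq)
  if (side == "L") {
    s <- max(0L, pos - flank)
    piece <- as.character(Biostrings::subseq(seq, s + 1L, pos))
    if (junction_edge == "left")  # junction must sit at left edge: flip
      piece <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(piece)))
  } else {
    e <- min(len, pos + flank)
    piece <- as.character(Biostrings::subseq(seq, pos + 1L, e))
    if (junction_edge == "right")
      piece <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(piece)))
  }
  piece
}

#' Tabular overview of called fusions
#'
#' One row per fusion with the fixed column set: `gene5`, `gene3`,
#' `locus5`, `locus3`, `bp5`, `bp3` (1-based `chrom:pos` anchored on the
#' retained base), `support` (distinct reads), `cds5_len`, `cds3_len`,
#' `fused_cds_len`, `flags` (";"-joined, "." when none), `primer_fwd`,
#' `primer_rev`. Support counts here can be lower than raw per-junction
#' read counts because a read supporting a junction multiple times is a
#' single supporting read.
#'
#' @param fusions list of composed `FusionCall`s
#' @param path optional TSV output path
#' @return data.frame (invisibly when `path` is given)
#' @export
fusion_overview <- function(fusions, path = NULL) {
  rows <- lapply(fusions, function(fu) {
    data.frame(
      gene5 = fu$gene5$name, gene3 = fu$gene3$name,
      locus5 = fu$locus5, locus3 = fu$locus3,
      bp5 = paste0(fu$chrom5, ":", vcf_pos(fu$bp5, fu$side5)),
      bp3 = paste0(fu$chrom3, ":", vcf_pos(fu$bp3, fu$side3)),
      support = fu$support,
      cds5_len = fu$cds5_len, cds3_len = fu$cds3_len,
      fused_cds_len = fu$fused_cds_len,
      flags = if (length(fu$flags) > 0) paste(sort(fu$flags), collapse = ";")
              else ".",
      primer_fwd = if (!is.null(fu$primers)) fu$primers$fwd else NA_character_,
      primer_rev = if (!is.null(fu$primers)) fu$primers$rev else NA_character_,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene5 = character(), gene3 = character(),
               locus5 = character(), locus3 = character(),
               bp5 = character(), bp3 = character(), support = integer(),
               cds5_len = integer(), cds3_len = integer(),
               fused_cds_len = integer(), flags = character(),
               primer_fwd = character(), primer_rev = character(),
               stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Parse a fusion overview TSV back into a data.frame
#' @param path TSV written by [fusion_overview()]
#' @return data.frame with the overview columns
#' @export
read_fusion_overview <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(support = "integer"))
}

#' @export
print.FusionCall <- function(x, ...) {
  cat(sprintf("%s: %s (5') -> %s (3')  %s:%d | %s:%d  support=%d  fused CDS %d bp%s\n",
              if (!is.null(x$id)) x$id else "FusionCall",
              x$gene5$name, x$gene3$name, x$chrom5, x$bp5, x$chrom3,
              x$bp3, x$support,
              if (!is.null(x$fused_cds_len)) x$fused_cds_len else NA,
              if (length(x$flags) > 0)
                paste0("  [", paste(x$flags, collapse = ";"), "]") else ""))
  invisible(x)
}
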