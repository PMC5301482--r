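#' Global pairwise alignment of two DNA sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap penalty of 2 per base (Biostrings backend; deterministic).
#'
#' @param a,b DNA strings.
#' @return list with `a_aln`, `b_aln` (equal-length aligned strings with
#'   `-` gaps) and `score`.
#' @export
align_pair <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  list(a_aln = as.character(Biostrings::alignedPattern(aln)),
       b_aln = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Construct a homolog group
#'
#' A cluster of homologous CDS across species, the unit of cross-species
#' comparison. Members carry the spliced CDS in transcript orientation
#' plus (optionally) the per-offset genomic position map from
#' [cds_transcript()].
#'
#' @param group_id gene name shared across species (e.g. "cox3").
#' @param members named list (by species id) of either CDS strings or
#'   lists with `seq` (and optionally `positions`, `strand`).
#' @return object of class `homolog_group`.
#' @export
homolog_group <- function(group_id, members) {
  if (length(members) < 2L) stopf("a homolog group needs >= 2 members")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stopf("members must be named by species id")
  members <- lapply(members, function(m) {
    if (is.character(m)) m <- list(seq = m)
    if (is.null(m$seq) || nchar(m$seq) == 0L)
      stopf("empty homolog-group member")
    m
  })
  structure(list(group_id = group_id, members = members),
            class = "homolog_group")
}

# alignment of one member against the center, digested into:
#  ins[c]: member bases inserted before center base c (c in 1..L+1)
#  at[c]:  member offset aligned to center base c (NA on member gap)
digest_vs_center <- function(member_seq, center_seq) {
  aln <- align_pair(member_seq, center_seq)
  m <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
  ctr <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
  L <- nchar(center_seq)
  ins <- integer(L + 1L)
  at <- rep(NA_integer_, L)
  mi <- 0L; ci <- 0L
  for (j in seq_along(ctr)) {
    if (ctr[j] == "-") {
      mi <- mi + 1L
      ins[ci + 1L] <- ins[ci + 1L] + 1L
    } else {
      ci <- ci + 1L
      if (m[j] != "-") { mi <- mi + 1L; at[ci] <- mi }
    }
  }
  list(ins = ins, at = at)
}

#' Center-star multiple alignment of a homolog group
#'
#' Each member is globally aligned ([align_pair()]) to the center — the
#' member with the maximal summed pairwise alignment score against the
#' others (ties to the first listed) — and the pairwise alignments are
#' merged on the center's coordinates. The result maps every member
#' offset to a consensus column; removing the gaps of any member's
#' column vector reproduces its CDS length.
#'
#' @param group `homolog_group`.
#' @return object of class `consensus_map`: list with `group_id`,
#'   `n_col` and `offsets` (named list per species: integer vector of
#'   length `n_col`, CDS offset or `NA` per column).
#' @export
align_group <- function(group) {
  mem <- group$members
  nm <- names(mem)
  n <- length(mem)
  score_sum <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    score_sum[i] <- score_sum[i] +
      align_pair(mem[[i]]$seq, mem[[j]]$seq)$score
  center <- which.max(score_sum)  # first index on ties
  cseq <- mem[[center]]$seq
  L <- nchar(cseq)
  dig <- lapply(mem, function(m) digest_vs_center(m$seq, cseq))
  W <- Reduce(pmax, lapply(dig, `[[`, "ins"))
  n_col <- sum(W) + L
  # column layout: [slot 1][center 1][slot 2][center 2]...[slot L+1]
  slot_start <- cumsum(c(1L, W + c(rep(1L, L), 0L)))[seq_len(L + 1L)]
  center_col <- slot_start[seq_len(L)] + W[seq_len(L)]
  offsets <- lapply(dig, function(d) {
    v <- rep(NA_integer_, n_col)
    v[center_col] <- d$at
    for (c in which(d$ins > 0L)) {
      k <- d$ins[c]
      # member bases inserted before center base c, left-aligned in slot
      prev <- if (c == 1L) 0L else {
        w <- which(!is.na(d$at[seq_len(c - 1L)]))
        if (length(w) == 0L) 0L else d$at[max(w)]
      }
      # offsets of inserted bases: the k bases preceding the next aligned one
      nxt <- if (c <= L && !is.na(d$at[c])) d$at[c] else NA_integer_
      ins_off <- if (!is.na(nxt)) (nxt - k):(nxt - 1L)
                 else (prev + 1L):(prev + k)
      v[slot_start[c] + seq_len(k) - 1L] <- ins_off
    }
    v
  })
  names(offsets) <- nm
  structure(list(group_id = group$group_id, n_col = n_col,
                 offsets = offsets, center = nm[center]),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map '%s': %d columns, %d members (center %s)\n",
              x$group_id, x$n_col, length(x$offsets), x$center))
  invisible(x)
}

# consensus column of one CDS offset for one species
offset_to_column <- function(map, species, cds_offset) {
  offs <- map$offsets[[species]]
  if (is.null(offs))
    stopf("species '%s' not in consensus map '%s'", species, map$group_id)
  if (cds_offset > max(offs, na.rm = TRUE) || cds_offset < 1L)
    stopf("cds_offset %d outside member map of '%s' (%s)", cds_offset,
          map$group_id, species)
  which(offs == cds_offset)
}

#' Cluster editing sites across species on consensus coordinates
#'
#' CDS sites from different species belong to one cluster iff they fall
#' in the same homolog group, align to the same consensus column, carry
#' the same RNA-space substitution, and have the same orientation class
#' (sense/antisense are tracked separately). Species whose member shows
#' a gap at a column are simply absent from clusters there.
#'
#' @param per_species_sites named list (by species) of annotated site
#'   tables (need `gene_id`, `cds_offset`, `rna_ref`, `rna_alt`,
#'   `orientation`, `region`).
#' @param consensus_maps named list (by group id) of `consensus_map`s.
#' @return data.frame: `group_id`, `column`, `orientation`,
#'   `substitution`, one logical column per species, `n_species`.
#' @export
conserved_sites <- function(per_species_sites, consensus_maps) {
  species <- names(per_species_sites)
  rows <- list()
  for (sp in species) {
    s <- per_species_sites[[sp]]
    s <- s[!is.na(s$cds_offset) & s$region == "CDS" &
             s$gene_id %in% names(consensus_maps), , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      map <- consensus_maps[[s$gene_id[i]]]
      col <- offset_to_column(map, sp, s$cds_offset[i])
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = s$gene_id[i], column = col,
        orientation = s$orientation[i],
        substitution = paste0(s$rna_ref[i], ">", s$rna_alt[i]),
        species = sp, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(group_id = character(0), column = integer(0),
                      orientation = character(0),
                      substitution = character(0), n_species = integer(0),
                      stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  key <- paste(long$group_id, long$column, long$orientation,
               long$substitution, sep = "|")
  ukey <- unique(key)
  out <- long[match(ukey, key), c("group_id", "column", "orientation",
                                  "substitution"), drop = FALSE]
  for (sp in species)
    out[[sp]] <- ukey %in% key[long$species == sp]
  out$n_species <- rowSums(as.matrix(out[, species, drop = FALSE]))
  out <- out[order(out$group_id, out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate SRE pairs with gene, CDS offset and sense substitution
#'
#' Projects each SRE position into its gene's spliced CDS and records
#' the sense-strand member's substitution (the pair's mirror identity).
#' Pairs outside CDS are dropped.
#'
#' @param sre_pairs data.frame from [pair_sre()].
#' @param genome named character vector (one contig).
#' @param models `gene_models`.
#' @return data.frame: `position`, `gene_id`, `cds_offset`,
#'   `sense_sub`.
#' @export
annotate_sre <- function(sre_pairs, genome, models) {
  gseq <- unname(genome[[1]])
  rows <- list()
  for (i in seq_len(nrow(sre_pairs))) {
    loc <- locate_one(sre_pairs$position[i], "F", models)
    if (loc$region != "CDS") next
    tr <- cds_transcript(gseq, models, loc$gene_id)
    off <- match(sre_pairs$position[i], tr$positions)
    sense_is_f <- loc$orientation == "sense"  # F queried above
    sub <- if (sense_is_f)
      paste0(sre_pairs$f_rna_ref[i], ">", sre_pairs$f_rna_alt[i])
    else
      paste0(sre_pairs$r_rna_ref[i], ">", sre_pairs$r_rna_alt[i])
    rows[[length(rows) + 1L]] <- data.frame(
      position = sre_pairs$position[i], gene_id = loc$gene_id,
      cds_offset = off, sense_sub = sub, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(0), gene_id = character(0),
                      cds_offset = integer(0), sense_sub = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cluster SRE events across species on consensus coordinates
#'
#' SRE positions cluster iff they share homolog group, consensus column
#' and mirror-type identity (the sense substitution). Pairwise and
#' all-species membership counts are reported alongside the clusters.
#'
#' @param per_species_sre named list (by species) of annotated SRE
#'   tables ([annotate_sre()]: `gene_id`, `cds_offset`, `sense_sub`).
#' @param consensus_maps named list of `consensus_map`s.
#' @return list with `clusters` (data.frame like [conserved_sites()]),
#'   `pairwise` (named counts "spA&spB") and `all_species` (count of
#'   clusters shared by every species).
#' @export
conserved_sre <- function(per_species_sre, consensus_maps) {
  species <- names(per_species_sre)
  as_sites <- lapply(per_species_sre, function(s) {
    if (nrow(s) == 0L)
      return(data.frame(gene_id = character(0), cds_offset = integer(0),
                        rna_ref = character(0), rna_alt = character(0),
                        orientation = character(0), region = character(0),
                        stringsAsFactors = FALSE))
    data.frame(gene_id = s$gene_id, cds_offset = s$cds_offset,
               rna_ref = sub(">.*", "", s$sense_sub),
               rna_alt = sub(".*>", "", s$sense_sub),
               orientation = "sre", region = "CDS",
               stringsAsFactors = FALSE)
  })
  cl <- conserved_sites(as_sites, consensus_maps)
  pairs <- utils::combn(species, 2L, paste, collapse = "&")
  pairwise <- setNames(integer(length(pairs)), pairs)
  if (nrow(cl) > 0L) {
    pw <- utils::combn(species, 2L, simplify = FALSE)
    for (i in seq_along(pw))
      pairwise[i] <- sum(cl[[pw[[i]][1]]] & cl[[pw[[i]][2]]])
  }
  all_sp <- if (nrow(cl) == 0L) 0L
            else sum(cl$n_species == length(species))
  list(clusters = cl, pairwise = pairwise, all_species = all_sp)
}

#' Cross-check editing sites between a sequence copy and its source
#'
#' For a paralogous copy of a region (e.g. a nuclear insertion of
#' mitochondrial DNA), translates each site called on the copy through a
#' global pairwise alignment to the source coordinates and flags it when
#' an identical site (same substitution, same strand class) was called
#' on the source. Sites at columns where copy and source bases differ
#' are not comparable and are skipped, as are sites opposite alignment
#' gaps (with a warning).
#'
#' @param sites_primary site table on the source (positions in
#'   `source_seq` coordinates, 1-based).
#' @param sites_copy site table on the copy (positions in `copy_seq`
#'   coordinates, 1-based).
#' @param copy_seq,source_seq the two sequences; their global alignment
#'   defines the coordinate translation.
#' @return data.frame: `copy_position`, `source_position` (NA when not
#'   translatable), `comparable`, `flagged`.
#' @export
crosscheck_paralog <- function(sites_primary, sites_copy, copy_seq,
                               source_seq) {
  aln <- align_pair(copy_seq, source_seq)
  cp <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
  sr <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
  cp_pos <- cumsum(cp != "-"); cp_pos[cp == "-"] <- NA
  sr_pos <- cumsum(sr != "-"); sr_pos[sr == "-"] <- NA
  pkeys <- paste(sites_primary$position, sites_primary$strand_group,
                 sites_primary$rna_ref, sites_primary$rna_alt, sep = ":")
  n_skip <- 0L
  rows <- lapply(seq_len(nrow(sites_copy)), function(i) {
    p <- sites_copy$position[i]
    col <- match(p, cp_pos)
    if (is.na(col)) { n_skip <<- n_skip + 1L
      return(data.frame(copy_position = p, source_position = NA_integer_,
                        comparable = FALSE, flagged = FALSE)) }
    if (is.na(sr_pos[col])) { n_skip <<- n_skip + 1L
      return(data.frame(copy_position = p, source_position = NA_integer_,
                        comparable = FALSE, flagged = FALSE)) }
    comparable <- cp[col] == sr[col]
    key <- paste(sr_pos[col], sites_copy$strand_group[i],
                 sites_copy$rna_ref[i], sites_copy$rna_alt[i], sep = ":")
    data.frame(copy_position = p, source_position = sr_pos[col],
               comparable = comparable,
               flagged = comparable && key %in% pkeys)
  })
  if (n_skip > 0L)
    warnf("%d site(s) not translatable through the alignment (gap/overhang)",
          n_skip)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutate a CDS into a diverged homolog with an offset map
#'
#' Synthetic-species helper: applies random substitutions at the given
#' divergence and occasional in-frame (codon) indels, returning the
#' derived sequence plus the map from ancestral CDS offsets to derived
#' offsets (`NA` where deleted). Start and stop codons are preserved.
#'
#' @param cds ancestral CDS string (length a multiple of 3).
#' @param divergence per-base substitution probability.
#' @param codon_indel_rate per-codon probability of an indel event
#'   (insertion or deletion of one codon).
#' @param seed RNG seed.
#' @return list with `seq`, `offset_map` (integer vector over ancestral
#'   offsets).
#' @export
mutate_cds <- function(cds, divergence = 0.02, codon_indel_rate = 0.01,
                       seed = 1L) {
  set.seed(seed)
  if (nchar(cds) %% 3L != 0L) stopf("CDS length not divisible by 3")
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mut <- which(runif(n) < divergence)
  mut <- mut[mut > 3L & mut <= n - 3L]  # keep start/stop intact
  chars[mut] <- vapply(chars[mut], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
  n_codon <- n %/% 3L
  out <- character(0); omap <- integer(0); cursor <- 0L
  for (ci in seq_len(n_codon)) {
    idx <- (3L * ci - 2L):(3L * ci)
    ev <- if (ci > 1L && ci < n_codon && runif(1) < codon_indel_rate)
      sample(c("del", "ins"), 1L) else "none"
    if (ev == "del") { omap[idx] <- NA_integer_; next }
    if (ev == "ins") {
      out <- c(out, sample(DNA_BASES, 3L, replace = TRUE))
      cursor <- cursor + 3L
    }
    out <- c(out, chars[idx])
    omap[idx] <- cursor + 1:3
    cursor <- cursor + 3L
  }
  list(seq = paste(out, collapse = ""), offset_map = omap)
}
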