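#' Two-person pedigree relationships
#'
#' An `ibd_pedigree` holds a pedigree together with an ordered pair of
#' members whose relatedness is studied. Parent links must be acyclic and
#' every non-founder has both parents in the pedigree. Only outbred
#' pedigrees for which the pair has zero probability of sharing both
#' haplotypes (kappa2 = 0) are accepted: with continuously observed IBD
#' restricted to the states IBD0/IBD1, relationships such as full siblings
#' (whose kappa2 is positive) are out of scope and rejected at
#' construction.
#'
#' @param id character or integer vector of member identifiers.
#' @param father,mother parent identifiers per member; `NA` (or `"0"`) for
#'   founders. A member has either both parents or none.
#' @param pair length-2 vector naming the two members whose relationship is
#'   modelled.
#' @param sex optional sex codes (1 = male, 2 = female, 0 = unknown); kept
#'   for PED round-trips, not used by the IBD model.
#' @param check_kappa2 if `TRUE` (default) reject pedigrees where the pair
#'   can be IBD2.
#'
#' @return An object of class `ibd_pedigree` with components `id`,
#'   `father_idx`, `mother_idx`, `founders`, `nnf` (number of non-founders),
#'   `pair` (indices), `meioses` (one row per meiosis in the frozen bit
#'   order), and the relevant-meiosis reduction used by all exact
#'   computations.
#' @seealso [relationship()] for named relationships, [read_ped()] for
#'   PED-like files.
#' @export
ibd_pedigree <- function(id, father, mother, pair, sex = NULL,
                         check_kappa2 = TRUE) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) {
    stop("duplicated member identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  norm_parent <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", "NA") | is.na(p)] <- NA_character_
    p
  }
  father <- norm_parent(father)
  mother <- norm_parent(mother)
  if (length(father) != n || length(mother) != n) {
    stop("father/mother must have one entry per member")
  }
  if (any(is.na(father) != is.na(mother))) {
    stop("every non-founder needs exactly two parents; members with one ",
         "parent: ", paste(id[is.na(father) != is.na(mother)], collapse = ", "))
  }
  fidx <- match(father, id)
  midx <- match(mother, id)
  bad <- (!is.na(father) & is.na(fidx)) | (!is.na(mother) & is.na(midx))
  if (any(bad)) {
    stop("parents not in pedigree for member(s): ",
         paste(id[bad], collapse = ", "))
  }
  if (length(pair) != 2L) stop("pair must name exactly two members")
  pair <- as.character(pair)
  pidx <- match(pair, id)
  if (anyNA(pidx)) stop("pair member(s) not in pedigree: ",
                        paste(pair[is.na(pidx)], collapse = ", "))
  if (pidx[1] == pidx[2]) stop("the two pair members must be distinct")

  ord <- topo_order(fidx, midx)   # errors on cycles

  nonf <- which(!is.na(fidx))
  nnf <- length(nonf)

  # inbreeding check: a member is inbred if its parents share an ancestor
  anc <- ancestor_sets(fidx, midx, ord)
  for (j in nonf) {
    pa <- c(fidx[j], anc[[fidx[j]]])
    ma <- c(midx[j], anc[[midx[j]]])
    if (length(intersect(pa, ma)) > 0) {
      stop("inbred pedigree: parents of member '", id[j],
           "' share an ancestor; inbred pedigrees are not supported")
    }
  }

  # meiosis table in the frozen bit order: sorted by child index,
  # paternal before maternal (bit k of an IBD vector addresses row k+1)
  nonf_sorted <- sort(nonf)
  meioses <- data.frame(
    child  = rep(nonf_sorted, each = 2L),
    parent = as.integer(rbind(fidx[nonf_sorted], midx[nonf_sorted])),
    type   = rep(c("paternal", "maternal"), times = nnf),
    stringsAsFactors = FALSE
  )

  ped <- structure(
    list(id = id, father_idx = fidx, mother_idx = midx,
         founders = which(is.na(fidx)), nnf = nnf, pair = pidx,
         sex = if (is.null(sex)) rep(0L, n) else as.integer(sex),
         meioses = meioses, topo = ord,
         label = paste(pair, collapse = "-"),
         cache = new.env(parent = emptyenv())),
    class = "ibd_pedigree"
  )
  ped$relevant <- relevant_meioses(ped)

  if (check_kappa2) {
    kap <- identity_coefficients(ped)
    if (kap$k2 > 0) {
      stop("relationship has nonzero IBD2 probability (kappa2 = ",
           format(kap$k2), "); only IBD0/IBD1-capable pairs are supported ",
           "(full siblings and other IBD2-capable states are out of scope)")
    }
  }
  ped
}

# Kahn-style topological order, parents before children; errors on cycles.
topo_order <- function(fidx, midx) {
  n <- length(fidx)
  indeg <- integer(n)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(fidx[j], midx[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        children[[p]] <- c(children[[p]], j)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != n) stop("parent links contain a cycle")
  out
}

ancestor_sets <- function(fidx, midx, ord) {
  anc <- vector("list", length(fidx))
  for (j in ord) {
    if (is.na(fidx[j])) {
      anc[[j]] <- integer(0)
    } else {
      anc[[j]] <- unique(c(fidx[j], midx[j], anc[[fidx[j]]], anc[[midx[j]]]))
    }
  }
  anc
}

# Identify meioses whose transmission choice can affect the pair's IBD
# state. A meiosis parent -> child matters only when (i) the child is an
# ancestor of (or is) one of the pair, and (ii) the parent carries labels
# that can be shared by both pair members, i.e. the parent is, or descends
# from, a common ancestor of the pair. All other bits are frozen to 0; the
# observable IBD process is unchanged (the discarded bits toggle labels
# that can never be shared).
relevant_meioses <- function(ped) {
  anc <- ancestor_sets(ped$father_idx, ped$mother_idx, ped$topo)
  a <- ped$pair[1]; b <- ped$pair[2]
  A <- c(a, anc[[a]]); B <- c(b, anc[[b]])
  AB <- union(A, B)
  C <- intersect(A, B)
  carrier <- vapply(seq_along(ped$id), function(m) {
    m %in% C || length(intersect(anc[[m]], C)) > 0
  }, logical(1))
  rel <- ped$meioses$child %in% AB & carrier[ped$meioses$parent]
  which(rel)
}

#' @export
print.ibd_pedigree <- function(x, ...) {
  cat("<ibd_pedigree> ", length(x$id), " members, ", x$nnf,
      " non-founders (", 2L * x$nnf, " meioses, ",
      length(x$relevant), " relevant)\n", sep = "")
  cat("  pair: ", x$id[x$pair[1]], " - ", x$id[x$pair[2]], "\n", sep = "")
  invisible(x)
}

#' Read a PED-like pedigree file
#'
#' One row per member with whitespace-separated columns family id, member
#' id, father id, mother id, sex (1/2/0); `0` marks a missing parent
#' (founder). All rows must belong to one family. The studied pair is
#' supplied separately.
#'
#' @param path file path.
#' @param pair character vector of the two member ids under study.
#' @inheritParams ibd_pedigree
#' @return an [ibd_pedigree()].
#' @export
read_ped <- function(path, pair, check_kappa2 = TRUE) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fam", "id", "father", "mother", "sex"),
                           colClasses = "character")
  if (length(unique(tab$fam)) != 1L) {
    stop("PED file must contain exactly one family (found ",
         length(unique(tab$fam)), ")")
  }
  ibd_pedigree(tab$id, tab$father, tab$mother, pair = pair,
               sex = as.integer(tab$sex), check_kappa2 = check_kappa2)
}

#' Write a pedigree in PED-like format
#'
#' @param ped an [ibd_pedigree()].
#' @param path output file.
#' @param fam family identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, fam = "1") {
  father <- ifelse(is.na(ped$father_idx), "0", ped$id[ped$father_idx])
  mother <- ifelse(is.na(ped$mother_idx), "0", ped$id[ped$mother_idx])
  tab <- data.frame(fam = fam, id = ped$id, father = father, mother = mother,
                    sex = ped$sex)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
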