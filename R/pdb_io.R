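#' Read a rigid body from a PDB file (C-alpha reduction)
#'
#' Reads coordinates with bio3d, keeps C-alpha atoms only (one bead per
#' residue) and resolves anchor addresses of the form `"A:345:CA"`
#' (chain:residue number:atom name) to bead indices.
#'
#' @param path PDB file path.
#' @param body_id body label (default: file name without extension).
#' @param anchors named character vector, anchor name -> `"chain:resno:atom"`.
#' @param weight per-bead scattering weight (default 1; e.g. 1.4 for a
#'   glycan body, a crude allowance for its higher effective contrast).
#' @return A [rigid_body_spec] centred on its centroid, with the original
#'   centroid stored as attribute `origin`.
#' @export
read_body_pdb <- function(path, body_id = sub("\\.pdb$", "", basename(path)),
                          anchors = character(), weight = 1) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) < 1) stop("no C-alpha atoms in ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  idx <- integer(0)
  if (length(anchors)) {
    idx <- vapply(anchors, function(a) {
      f <- strsplit(a, ":")[[1]]
      if (length(f) != 3) stop("bad anchor address (want chain:resno:atom): ", a)
      hit <- which(at$chain == f[1] & at$resno == as.integer(f[2]) &
                     trimws(at$elety) == f[3])
      if (!length(hit)) stop("anchor not found in ", basename(path), ": ", a)
      hit[1]
    }, integer(1))
    names(idx) <- names(anchors)
  }
  origin <- colMeans(xyz)
  out <- rigid_body_spec(body_id, sweep(xyz, 2, origin), weight = weight,
                         anchors = idx)
  attr(out, "origin") <- origin
  out
}

#' Write a realized bead model as a PDB file
#'
#' One chain per protomer, one CA pseudo-atom per bead; anchor beads are
#' listed in REMARK records by name.
#'
#' @param model a [bead_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  n <- nrow(model$xyz)
  prot <- model$protomer_id
  chains <- LETTERS[((prot - 1L) %% 26L) + 1L]
  resno <- stats::ave(seq_len(n), prot, FUN = seq_along)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, chains, resno %% 10000L,
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3])
  rem <- if (length(model$anchors))
    sprintf("REMARK 280 ANCHOR %s BEAD %d", names(model$anchors),
            model$anchors) else character(0)
  writeLines(c(rem, lines, "END"), path)
  invisible(path)
}
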