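#' @include AllClasses.R
NULL

#' Construct, apply and combine rigid transforms
#'
#' \code{identityTransform} returns the identity;
#' \code{composeTransforms(b, a)} returns the transform equivalent to
#' applying \code{a} first and then \code{b}; \code{invertTransform}
#' inverts; \code{applyTransform} maps an n x 3 coordinate matrix or the
#' coordinates of a \linkS4class{StructureModel}.
#'
#' @param a,b,transform \linkS4class{RigidTransform} objects.
#' @param x An n x 3 numeric matrix or a \linkS4class{StructureModel}.
#' @return A \linkS4class{RigidTransform}, or the transformed coordinates /
#'   structure for \code{applyTransform}.
#' @name transforms
NULL

#' @rdname transforms
#' @export
identityTransform <- function()
  new("RigidTransform", rotation = diag(3), translation = numeric(3))

#' @rdname transforms
#' @export
composeTransforms <- function(b, a) {
  stopifnot(is(a, "RigidTransform"), is(b, "RigidTransform"))
  new("RigidTransform",
      rotation = b@rotation %*% a@rotation,
      translation = as.vector(b@rotation %*% a@translation) +
        b@translation)
}

#' @rdname transforms
#' @export
invertTransform <- function(transform) {
  stopifnot(is(transform, "RigidTransform"))
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.vector(-Rt %*% transform@translation))
}

#' @rdname transforms
#' @export
applyTransform <- function(transform, x) {
  stopifnot(is(transform, "RigidTransform"))
  if (is(x, "StructureModel")) {
    xyz <- applyTransform(transform, coords(x))
    a <- x@atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    return(new("StructureModel", atoms = a, modelIndex = x@modelIndex))
  }
  x <- rbind(x)  # allow a bare length-3 vector
  x %*% t(transform@rotation) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid superposition of a mobile point set onto a reference
#' via singular value decomposition of the cross-covariance, constrained to
#' a proper rotation (no reflection). Returns the transform and the RMSD of
#' the superposed points. This is the operation used to align toxin
#' structures on their cystine Calpha atoms.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows,
#'   n >= 3.
#' @return list with \code{transform} (\linkS4class{RigidTransform}) and
#'   \code{rmsd} (Angstrom).
#' @examples
#' p <- matrix(rnorm(18), 6, 3)
#' kabschSuperpose(p, p)$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have matching dimensions",
         call. = FALSE)
  if (ncol(mobile) != 3L || nrow(mobile) < 3L)
    stop("need n x 3 coordinate matrices with n >= 3", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  if (d < 0)
    warning("optimal superposition required a reflection; ",
            "restricted to the best proper rotation")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- new("RigidTransform", rotation = R,
            translation = as.vector(cr - R %*% cm))
  moved <- applyTransform(tr, mobile)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' Extract Calpha coordinates for a residue selection
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param chain Chain identifier.
#' @param resno Residue numbers, in the order the rows are wanted.
#' @return n x 3 matrix of Calpha coordinates.
#' @export
caCoords <- function(structure, chain, resno) {
  a <- structure@atoms
  sel <- a[a$chain == chain & a$elety == "CA", , drop = FALSE]
  idx <- match(resno, sel$resno)
  if (anyNA(idx))
    stop("missing Calpha for residue(s): ",
         paste(resno[is.na(idx)], collapse = ", "), " in chain ", chain,
         call. = FALSE)
  as.matrix(sel[idx, c("x", "y", "z")])
}

# ---- solvent-accessible surface area (Shrake-Rupley) ----

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere-point quadrature: each atom's
#' solvent sphere (vdW radius + probe) is sampled on a Fibonacci lattice
#' and a point counts as accessible when it lies outside every neighbor's
#' solvent sphere. No randomness is involved, so results are reproducible
#' bit for bit. An atom coinciding exactly (position and radius) with a
#' lower-index atom is treated as fully occluded by it, so duplicated
#' atoms do not double-count area.
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param nPoints Quadrature points per atom (default 960; >= 92
#'   required).
#' @return A \linkS4class{SasaReport}.
#' @examples
#' toy <- simToyComplex(helixLength = 8, toxinAtomCount = 8)
#' shrakeRupleySasa(toy, nPoints = 240)
#' @export
shrakeRupleySasa <- function(structure, probe = 1.4, nPoints = 960L) {
  stopifnot(is(structure, "StructureModel"))
  .assertNumber(probe, "probe", 0)
  if (nPoints < 92L) stop("nPoints must be >= 92", call. = FALSE)
  a <- structure@atoms
  n <- nrow(a)
  xyz <- coords(structure)
  rs <- a$radius + probe
  pts <- .fibonacciSphere(as.integer(nPoints))
  sasa <- numeric(n)
  # exact duplicates: occluded by the copy with the lower index
  key <- paste(a$x, a$y, a$z, a$radius)
  dupOf <- match(key, key)
  for (i in seq_len(n)) {
    if (dupOf[i] < i) next  # duplicate of an earlier atom: SASA 0
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rs[i] + a$radius + probe & seq_len(n) != i &
                dupOf == seq_len(n))
    sp <- pts * rs[i] + matrix(xyz[i, ], nPoints, 3, byrow = TRUE)
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rs[j]^2 - 1e-9
      if (!any(acc)) break
    }
    sasa[i] <- 4 * pi * rs[i]^2 * sum(acc) / nPoints
  }
  atomsTab <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                         elety = a$elety, sasa = sasa)
  resTab <- stats::aggregate(sasa ~ chain + resno + resid, data = atomsTab,
                             FUN = sum)
  resTab <- resTab[order(resTab$chain, resTab$resno), , drop = FALSE]
  rownames(resTab) <- NULL
  new("SasaReport", probe = probe, nPoints = as.integer(nPoints),
      atoms = atomsTab, residues = resTab, total = sum(sasa))
}

#' Per-residue interface burial (DSASA)
#'
#' SASA of the selected component extracted alone minus the SASA of the
#' same residues inside the complex, computed with identical probe and
#' quadrature so the two states are directly comparable. Positive values
#' mark burial at the binding interface; residues are returned ranked by
#' decreasing DSASA.
#'
#' @param complex \linkS4class{StructureModel} containing all chains.
#' @param componentChains Chains forming the component of interest (e.g.
#'   the toxin).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param nPoints Quadrature points per atom (default 960).
#' @return A \linkS4class{DeltaSasaReport}.
#' @export
deltaSasa <- function(complex, componentChains, probe = 1.4,
                      nPoints = 960L) {
  stopifnot(is(complex, "StructureModel"))
  if (!length(componentChains))
    stop("componentChains must name at least one chain", call. = FALSE)
  a <- complex@atoms
  miss <- setdiff(componentChains, unique(a$chain))
  if (length(miss))
    stop("chain(s) not present in the complex: ",
         paste(miss, collapse = ", "), call. = FALSE)
  free <- new("StructureModel",
              atoms = a[a$chain %in% componentChains, , drop = FALSE],
              modelIndex = complex@modelIndex)
  sFree <- shrakeRupleySasa(free, probe, nPoints)@residues
  sCplx <- shrakeRupleySasa(complex, probe, nPoints)@residues
  sCplx <- sCplx[sCplx$chain %in% componentChains, , drop = FALSE]
  key <- function(d) paste(d$chain, d$resno)
  idx <- match(key(sFree), key(sCplx))
  res <- data.frame(chain = sFree$chain, resno = sFree$resno,
                    resid = sFree$resid, sasa_free = sFree$sasa,
                    sasa_complex = sCplx$sasa[idx])
  res$dsasa <- res$sasa_free - res$sasa_complex
  res <- res[order(-res$dsasa, res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  new("DeltaSasaReport", residues = res,
      componentChains = componentChains, probe = probe,
      nPoints = as.integer(nPoints))
}

#' Area of the largest connected hydrophobic patch
#'
#' Clusters the given hydrophobic residues by spatial contact (any
#' heavy-atom pair within \code{contactCutoff}) and returns the summed
#' per-residue SASA of the cluster with the greatest total area -- the
#' "hydrophobic surface" of the toxin.
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param residues data.frame with columns \code{chain} and \code{resno}
#'   naming the hydrophobic residue set.
#' @param sasa A \linkS4class{SasaReport} computed on \code{structure}.
#' @param contactCutoff Heavy-atom contact distance in Angstrom defining
#'   cluster connectivity (default 4.5).
#' @return Patch area in Angstrom^2, with the member residues attached as
#'   attribute \code{"members"}.
#' @export
hydrophobicPatchArea <- function(structure, residues, sasa,
                                 contactCutoff = 4.5) {
  stopifnot(is(structure, "StructureModel"), is(sasa, "SasaReport"))
  if (!nrow(residues)) stop("residue set is empty", call. = FALSE)
  a <- structure@atoms
  a <- a[a$element != "H", , drop = FALSE]
  keyA <- paste(a$chain, a$resno)
  keyR <- paste(residues$chain, residues$resno)
  present <- keyR %in% keyA
  if (!any(present))
    stop("residue set is disjoint from the structure", call. = FALSE)
  keyR <- keyR[present]
  m <- length(keyR)
  # residue adjacency from heavy-atom contacts
  adj <- matrix(FALSE, m, m)
  atomsOf <- lapply(keyR, function(k)
    as.matrix(a[keyA == k, c("x", "y", "z"), drop = FALSE]))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    d2 <- outer(rowSums(atomsOf[[i]]^2), rowSums(atomsOf[[j]]^2), "+") -
      2 * atomsOf[[i]] %*% t(atomsOf[[j]])
    if (min(d2) <= contactCutoff^2) adj[i, j] <- adj[j, i] <- TRUE
  }
  # connected components by breadth-first search
  comp <- rep(NA_integer_, m); cur <- 0L
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  resTab <- sasa@residues
  keyS <- paste(resTab$chain, resTab$resno)
  areaOf <- vapply(keyR, function(k) {
    hit <- match(k, keyS)
    if (is.na(hit)) 0 else resTab$sasa[hit]
  }, numeric(1))
  compArea <- tapply(areaOf, comp, sum)
  bestComp <- as.integer(names(compArea)[which.max(compArea)])
  out <- unname(max(compArea))
  attr(out, "members") <- keyR[comp == bestComp]
  out
}

# ---- helix geometry and register grafting ----

#' Estimate a helix axis from Calpha coordinates
#'
#' Least-squares line through sliding-window centroids of the Calpha trace
#' (window of one helical turn, so the helical wobble averages out),
#' oriented from the first residue towards the last.
#'
#' @param ca n x 3 matrix of consecutive Calpha coordinates, n >= 4.
#' @param twist Helical twist per residue in degrees, used to size the
#'   averaging window (default 100, canonical alpha-helix).
#' @return list with \code{point} (a point on the axis) and
#'   \code{direction} (unit vector).
#' @export
helixAxis <- function(ca, twist = 100) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4L)
    stop("need at least 4 residues to estimate a helix axis",
         call. = FALSE)
  w <- min(n, max(3L, as.integer(round(360 / twist))))
  cent <- t(vapply(seq_len(n - w + 1L), function(i)
    colMeans(ca[i:(i + w - 1L), , drop = FALSE]), numeric(3)))
  mid <- colMeans(cent)
  if (nrow(cent) < 2L) {
    dir <- ca[n, ] - ca[1, ]
  } else {
    dir <- svd(sweep(cent, 2, mid))$v[, 1]
  }
  if (sum(dir * (ca[n, ] - ca[1, ])) < 0) dir <- -dir
  list(point = mid, direction = dir / sqrt(sum(dir^2)))
}

# screw transform: rotate by angleDeg about the axis (point p, unit u) and
# translate by rise along u
.screwTransform <- function(p, u, angleDeg, rise) {
  th <- angleDeg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
  new("RigidTransform", rotation = R,
      translation = as.vector(p - R %*% p) + rise * u)
}

#' Graft a toxin onto a target helix at a register offset
#'
#' Places a toxin model against a target structure by (a) superposing the
#' toxin-bound template helix backbone (Calpha) onto the target helix at
#' the matched register, then (b) for nonzero offsets, stepping the
#' placement by \code{offset} elementary register steps, each a rotation of
#' \code{twistDeg} about the target helix axis plus a translation of
#' \code{riseA} along it. The template helix residues replace the target
#' helix residues in the combined model (the grafted segment), after which
#' steric clashes and interface residues between the toxin side and the
#' remaining target are reported.
#'
#' @param toxin \linkS4class{StructureModel} containing the toxin and its
#'   template helix.
#' @param target \linkS4class{StructureModel} containing the target helix.
#' @param templateChain,templateResnos Chain and residue numbers of the
#'   template helix within \code{toxin} (same length as
#'   \code{targetResnos}).
#' @param targetChain,targetResnos Chain and residue numbers of the target
#'   helix within \code{target}.
#' @param offset Integer register offset (0 = direct superposition;
#'   positive steps advance towards higher target residue numbers).
#' @param twistDeg Rotation per register step in degrees (default 100).
#' @param riseA Translation per register step in Angstrom (default 1.5,
#'   canonical alpha-helical rise; supply the value your geometry
#'   requires).
#' @param clashCutoff Heavy-atom clash distance in Angstrom (default 2.5).
#' @param interfaceThreshold Interface residue distance threshold in
#'   Angstrom (default 12).
#' @param replaceTarget Drop the target helix residues that the template
#'   replaces (default TRUE).
#' @return A \linkS4class{GraftModel}.
#' @export
graftByRegister <- function(toxin, target, templateChain, templateResnos,
                            targetChain, targetResnos, offset = 0L,
                            twistDeg = 100, riseA = 1.5,
                            clashCutoff = 2.5, interfaceThreshold = 12,
                            replaceTarget = TRUE) {
  stopifnot(is(toxin, "StructureModel"), is(target, "StructureModel"))
  if (length(templateResnos) != length(targetResnos))
    stop("template and target helix ranges must have equal length",
         call. = FALSE)
  offset <- as.integer(offset)
  tplCa <- caCoords(toxin, templateChain, templateResnos)
  tgtCa <- caCoords(target, targetChain, targetResnos)
  base <- kabschSuperpose(tplCa, tgtCa)$transform
  ax <- helixAxis(tgtCa, twist = twistDeg)
  step <- .screwTransform(ax$point, ax$direction, twistDeg, riseA)
  tr <- base
  if (offset != 0L) {
    one <- if (offset > 0L) step else invertTransform(step)
    for (k in seq_len(abs(offset))) tr <- composeTransforms(one, tr)
  }
  placed <- applyTransform(tr, toxin)
  tgtAtoms <- target@atoms
  if (replaceTarget)
    tgtAtoms <- tgtAtoms[!(tgtAtoms$chain == targetChain &
                           tgtAtoms$resno %in% targetResnos), ,
                         drop = FALSE]
  shared <- intersect(unique(tgtAtoms$chain), unique(placed@atoms$chain))
  if (length(shared))
    stop("toxin and target share chain id(s): ",
         paste(shared, collapse = ", "),
         "; rename chains before grafting", call. = FALSE)
  combined <- new("StructureModel",
                  atoms = rbind(tgtAtoms, placed@atoms))
  toxinChains <- unique(placed@atoms$chain)
  targetChains <- unique(tgtAtoms$chain)
  cl <- detectClashes(combined, toxinChains, targetChains,
                      cutoff = clashCutoff)
  iface <- interfaceResidues(combined, toxinChains, targetChains,
                             threshold = interfaceThreshold)
  new("GraftModel", offset = offset, transform = tr,
      structure = combined, clashCount = cl$count, clashes = cl$pairs,
      interface = iface, toxinChains = toxinChains,
      targetChains = targetChains)
}

#' Count steric clashes between two chain groups
#'
#' Inter-group heavy-atom pairs closer than \code{cutoff}. Pairs are
#' reported in a deterministic order (by first then second atom row).
#'
#' @param model A \linkS4class{StructureModel}.
#' @param chainsA,chainsB Chain identifier vectors for the two sides.
#' @param cutoff Clash distance in Angstrom (default 2.5).
#' @return list with \code{count} and a \code{pairs} data.frame
#'   (\code{chain_a}, \code{resno_a}, \code{elety_a}, \code{chain_b},
#'   \code{resno_b}, \code{elety_b}, \code{distance}).
#' @export
detectClashes <- function(model, chainsA, chainsB, cutoff = 2.5) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  ia <- which(a$chain %in% chainsA & a$element != "H")
  ib <- which(a$chain %in% chainsB & a$element != "H")
  if (!length(ia) || !length(ib))
    stop("both chain groups must be present in the model", call. = FALSE)
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(a[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  pairs <- data.frame(
    chain_a = a$chain[ia[hit[, 1]]], resno_a = a$resno[ia[hit[, 1]]],
    elety_a = a$elety[ia[hit[, 1]]],
    chain_b = a$chain[ib[hit[, 2]]], resno_b = a$resno[ib[hit[, 2]]],
    elety_b = a$elety[ib[hit[, 2]]],
    distance = sqrt(pmax(0, d2[hit])))
  list(count = nrow(pairs), pairs = pairs)
}

#' Interface residues between two chain groups
#'
#' Residues with any heavy atom within \code{threshold} of the partner
#' group; the default 12 Angstrom mirrors the masking convention used when
#' coloring binding-surface figures.
#'
#' @param model A \linkS4class{StructureModel}.
#' @param chainsA,chainsB Chain identifier vectors for the two sides.
#' @param threshold Distance threshold in Angstrom (> 0, default 12).
#' @return list of two data.frames (\code{a}, \code{b}) with columns
#'   \code{chain}, \code{resno}, \code{resid}, \code{min_distance}.
#' @export
interfaceResidues <- function(model, chainsA, chainsB, threshold = 12) {
  stopifnot(is(model, "StructureModel"))
  .assertNumber(threshold, "threshold", 0, strict = TRUE, upper = Inf)
  a <- model@atoms
  ia <- which(a$chain %in% chainsA & a$element != "H")
  ib <- which(a$chain %in% chainsB & a$element != "H")
  A <- as.matrix(a[ia, c("x", "y", "z")])
  B <- as.matrix(a[ib, c("x", "y", "z")])
  if (!length(ia) || !length(ib))
    return(list(a = data.frame(), b = data.frame()))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  side <- function(idx, dmin) {
    df <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                     resid = a$resid[idx], d = sqrt(dmin))
    agg <- stats::aggregate(d ~ chain + resno + resid, data = df,
                            FUN = min)
    agg <- agg[agg$d <= threshold, , drop = FALSE]
    agg <- agg[order(agg$chain, agg$resno), , drop = FALSE]
    names(agg)[names(agg) == "d"] <- "min_distance"
    rownames(agg) <- NULL
    agg
  }
  list(a = side(ia, apply(d2, 1, min)),
       b = side(ib, apply(d2, 2, min)))
}
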