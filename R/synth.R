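## Synthetic-data generators: labeled windows with planted index
## signal, toy multi-chain complexes with planted interface contacts,
## and motif families for clustering tests.  All generators are
## bit-reproducible per seed and emit their ground truth.

## Swiss-Prot-like background residue frequencies.
.SWISSPROT_FREQ <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546,
                     C = 0.0137, Q = 0.0393, E = 0.0674, G = 0.0708,
                     H = 0.0227, I = 0.0593, L = 0.0965, K = 0.0582,
                     M = 0.0241, F = 0.0386, P = 0.0472, S = 0.0660,
                     T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)

.background <- function(background = c("uniform", "swissprot")) {
    background <- match.arg(background)
    if (background == "uniform")
        stats::setNames(rep(1 / 20, 20L), .AA)
    else {
        f <- .SWISSPROT_FREQ[.AA]
        f / sum(f)
    }
}

.CENTER_RESIDUES <- list(
    acetylation = c(K = 1),
    methylation = c(K = 0.6, R = 0.4),
    `O-GalNAc` = c(S = 0.6, T = 0.4),
    `O-GlcNAc` = c(S = 0.6, T = 0.4),
    phosphorylation = c(S = 0.6, T = 0.25, Y = 0.15),
    sumoylation = c(K = 1),
    ubiquitylation = c(K = 1))

## Background-weighted residual of `v` against the columns of `V`
## (plus an intercept): the component of a property scale that the
## other supplied scales cannot explain.  Tilting along this residual
## plants class signal in the chosen scale while leaving the expected
## value of every other scale (approximately) untouched.
.bgResidual <- function(v, V, bg) {
    X <- cbind(intercept = rep(1, length(v)), V)
    beta <- solve(crossprod(X, bg * X), crossprod(X, bg * v))
    as.numeric(v - X %*% beta)
}

## Exponentially tilt `bg` so the expected value of `v` moves up by
## `shift` (in units of v's SD under bg).  Smooth single-knob class
## signal: p_a proportional to bg_a * exp(theta * v_a).
.tiltedFreq <- function(bg, v, shift) {
    mu <- sum(bg * v)
    sd0 <- sqrt(sum(bg * (v - mu)^2))
    if (shift == 0 || sd0 == 0) return(bg)
    z <- (v - mu) / sd0               # unit-SD scale keeps exp() finite
    target <- min(shift, 0.999 * max(z))
    f <- function(theta) {
        p <- bg * exp(theta * z)
        p <- p / sum(p)
        sum(p * z) - target
    }
    theta <- stats::uniroot(f, c(0, 100))$root
    p <- bg * exp(theta * z)
    p / sum(p)
}

#' Simulate labeled modification-site windows
#'
#' Outside-class residues are drawn from the background; inside-class
#' flank residues are drawn from the background exponentially tilted
#' so that a window's mean signal-scale value over its 14 flank
#' positions shifts upward by `effect_size` standard deviations of
#' that window mean (equivalently, each flank position shifts by
#' `effect_size/sqrt(14)` residue-level SDs).  The tilt is applied
#' along the component of the signal scale orthogonal (in the
#' background-weighted sense) to the other supplied scales, so the
#' planted signal is carried by the chosen scale and the remaining
#' scales stay (approximately) uninformative.  The centre residue
#' follows the modification-type convention (K for acetylation and
#' ubiquitylation, S/T/Y for phosphorylation, ...), identically in
#' both classes so that the class signal lives only in the flanks.
#'
#' @param n_inside,n_outside Window counts per class.
#' @param indices List of [AminoAcidIndex-class]; the encoding set.
#' @param signal_indices Accessions (within `indices`) carrying the
#'   class signal.
#' @param effect_size Mean shift in background-SD units (0 = null).
#' @param mod_type Modification type (sets the centre residue).
#' @param seed Integer seed.
#' @param background `"uniform"` (default) or `"swissprot"`.
#' @return Labeled window data.frame (`label` = `inside`/`outside`).
#' @export
simulateWindows <- function(n_inside, n_outside, indices = list(kdHydropathy()),
                            signal_indices = character(0), effect_size = 0,
                            mod_type = "phosphorylation", seed = 1L,
                            background = c("uniform", "swissprot")) {
    stopifnot(n_inside >= 0, n_outside >= 0, effect_size >= 0)
    if (is(indices, "AminoAcidIndex")) indices <- list(indices)
    accs <- vapply(indices, accession, character(1))
    bad <- setdiff(signal_indices, accs)
    if (length(bad))
        stop("unknown signal accession(s): ", paste(bad, collapse = ", "))
    if (!mod_type %in% names(.CENTER_RESIDUES))
        stop("unknown mod_type: ", mod_type)
    bg <- .background(match.arg(background))
    pin <- bg
    if (length(signal_indices) && effect_size > 0) {
        noise <- setdiff(accs, signal_indices)
        V <- if (length(noise))
            vapply(noise, function(a)
                indexValues(indices[[match(a, accs)]])[.AA],
                numeric(20L))
        else NULL
        ## effect_size is the shift of the window-level flank mean in
        ## SDs of that mean; with 14 iid flank draws the per-position
        ## shift is effect_size / sqrt(14) residue-level SDs.
        per_pos <- effect_size / sqrt(14) / length(signal_indices)
        for (acc in signal_indices) {
            v <- indexValues(indices[[match(acc, accs)]])[.AA]
            u <- .bgResidual(v, V, bg)
            pin <- .tiltedFreq(pin, u, per_pos)
        }
    }
    centre <- .CENTER_RESIDUES[[mod_type]]
    n <- n_inside + n_outside
    withr::with_seed(as.integer(seed), {
        drawFlanks <- function(nw, p) {
            if (!nw) return(character(0))
            m <- matrix(sample(.AA, nw * 14L, replace = TRUE, prob = p[.AA]),
                        nrow = nw)
            cent <- sample(names(centre), nw, replace = TRUE, prob = centre)
            apply(cbind(m[, 1:7, drop = FALSE], cent,
                        m[, 8:14, drop = FALSE]), 1L, paste, collapse = "")
        }
        seqs <- c(drawFlanks(n_inside, pin), drawFlanks(n_outside, bg))
    })
    data.frame(protein_id = sprintf("SIMP%05d", seq_len(n)),
               site_position = 8L,
               mod_type = mod_type,
               sequence = seqs,
               label = rep(c("inside", "outside"), c(n_inside, n_outside)),
               stringsAsFactors = FALSE)
}

#' Simulate a multi-chain complex with planted interface contacts
#'
#' Chains of single-Calpha residues are placed on a coarse grid whose
#' spacing guarantees no accidental Van der Waals overlap; each
#' planted pair then relocates the partner residue to within contact
#' distance of its target.  By construction exactly the planted
#' residue pairs violate the overlap rule and every other inter-chain
#' pair clears it by at least `margin` Angstrom.
#'
#' A partner residue (second element of a pair) may serve only one
#' target; targets may be shared across pairs.
#'
#' @param n_chains Number of chains (single letters A, B, ...).
#' @param residues_per_chain Residues per chain.
#' @param contact_pairs Either an integer count (pairs drawn between
#'   consecutive chains with fresh residues) or a data.frame with
#'   columns `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @param seed Integer seed.
#' @param radii,tolerance Contact rule parameters the geometry is
#'   built against.
#' @param margin Clearance (Angstrom) enforced for non-planted pairs.
#' @param structure_id Identifier for the emitted structure.
#' @return List: `structure` ([Structure-class]), `truth` (data.frame
#'   of planted pairs), `pdb` (PDB-format lines).
#' @export
simulateComplex <- function(n_chains = 2L, residues_per_chain = 10L,
                            contact_pairs = 3L, seed = 1L,
                            radii = vdwRadii(), tolerance = 0,
                            margin = 1, structure_id = "SYNTH") {
    stopifnot(n_chains >= 1L, residues_per_chain >= 1L)
    chains <- LETTERS[seq_len(n_chains)]
    rC <- radii[["C"]]
    spacing <- 2 * max(radii) + tolerance + margin + 3   # grid pitch
    ## lay out chains as parallel rows; residue identities are random
    ## so the derived chain sequences support exact 15-mer matching
    aa3 <- names(.AA3TO1)
    atoms <- withr::with_seed(as.integer(seed) + 7777L,
        do.call(rbind, lapply(seq_len(n_chains), function(ci)
            data.frame(chain = chains[ci],
                       resno = seq_len(residues_per_chain),
                       insert = "",
                       resid = sample(aa3, residues_per_chain,
                                      replace = TRUE),
                       elety = "CA",
                       element = "C",
                       x = seq_len(residues_per_chain) * spacing,
                       y = ci * 3 * spacing, z = 0,
                       occupancy = 1, stringsAsFactors = FALSE))))
    if (is.numeric(contact_pairs) && length(contact_pairs) == 1L) {
        np <- as.integer(contact_pairs)
        if (np > 0L && n_chains < 2L)
            stop("geometrically unsatisfiable: contacts need >= 2 chains")
        pairs <- if (np == 0L)
            data.frame(chain_a = character(0), resno_a = integer(0),
                       chain_b = character(0), resno_b = integer(0))
        else withr::with_seed(as.integer(seed), {
            if (np > residues_per_chain * (n_chains - 1L))
                stop("geometrically unsatisfiable: too many planted pairs")
            per <- tabulate(rep_len(seq_len(n_chains - 1L), np),
                            nbins = n_chains - 1L)
            do.call(rbind, lapply(seq_len(n_chains - 1L), function(ca) {
                if (!per[ca]) return(NULL)
                data.frame(chain_a = chains[ca],
                           resno_a = sample.int(residues_per_chain, per[ca]),
                           chain_b = chains[ca + 1L],
                           resno_b = sample.int(residues_per_chain, per[ca]),
                           stringsAsFactors = FALSE)
            }))
        })
    } else {
        pairs <- as.data.frame(contact_pairs)
        stopifnot(all(c("chain_a", "resno_a", "chain_b", "resno_b") %in%
                      names(pairs)))
    }
    if (nrow(pairs)) {
        if (any(pairs$chain_a == pairs$chain_b))
            stop("geometrically unsatisfiable: planted pairs must join different chains")
        pkey <- paste(pairs$chain_b, pairs$resno_b)
        if (anyDuplicated(pkey))
            stop("geometrically unsatisfiable: a partner residue may serve one target only")
        ## contact distance just below the overlap threshold
        d_contact <- 2 * rC + tolerance - 0.4
        dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0),
                      c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0))
        used <- list()
        for (i in seq_len(nrow(pairs))) {
            ta <- which(atoms$chain == pairs$chain_a[i] &
                        atoms$resno == pairs$resno_a[i])
            tb <- which(atoms$chain == pairs$chain_b[i] &
                        atoms$resno == pairs$resno_b[i])
            if (length(ta) != 1L || length(tb) != 1L)
                stop("planted pair references an absent residue")
            tkey <- paste(pairs$chain_a[i], pairs$resno_a[i])
            slot <- length(used[[tkey]]) + 1L
            if (slot > nrow(dirs))
                stop("geometrically unsatisfiable: too many partners for one target")
            used[[tkey]] <- c(used[[tkey]], slot)
            atoms[tb, c("x", "y", "z")] <-
                atoms[ta, c("x", "y", "z")] + dirs[slot, ] * d_contact
        }
    }
    s <- new("Structure", structureId = structure_id, atoms = atoms)
    ## verify the construction against the brute-force rule
    got <- detectContacts(s, radii, tolerance)
    gotkey <- paste(got$chain_a, got$resno_a, got$chain_b, got$resno_b)
    wantkey <- if (nrow(pairs))
        paste(pairs$chain_a, pairs$resno_a, pairs$chain_b, pairs$resno_b)
    else character(0)
    if (!setequal(gotkey, wantkey))
        stop("geometrically unsatisfiable: planted layout produced ",
             "unintended contacts")
    list(structure = s, truth = pairs, pdb = writeStructurePDB(s))
}

#' Simulate motif families of 15-mers
#'
#' Each family is defined by a random consensus 15-mer; at every
#' position a window takes the consensus letter with probability
#' `strength` and a uniform random residue otherwise.
#'
#' @param families Number of families.
#' @param n_per_family Windows per family.
#' @param strength Consensus probability in \[0, 1\] (0 = pure noise).
#' @param seed Integer seed.
#' @return List: `windows` (window data.frame, label `outside`),
#'   `family` (integer truth per window), `consensus` (character).
#' @export
simulateMotifFamilies <- function(families = 2L, n_per_family = 100L,
                                  strength = 0.8, seed = 1L) {
    stopifnot(families >= 1L, n_per_family >= 1L,
              strength >= 0, strength <= 1)
    withr::with_seed(as.integer(seed), {
        consensus <- vapply(seq_len(families), function(i)
            paste(sample(.AA, 15L, replace = TRUE), collapse = ""),
            character(1))
        seqs <- unlist(lapply(seq_len(families), function(fam) {
            cons <- strsplit(consensus[fam], "")[[1L]]
            vapply(seq_len(n_per_family), function(i) {
                take <- stats::runif(15L) < strength
                letters <- ifelse(take, cons,
                                  sample(.AA, 15L, replace = TRUE))
                paste(letters, collapse = "")
            }, character(1))
        }))
    })
    n <- families * n_per_family
    list(windows = data.frame(protein_id = sprintf("FAM%05d", seq_len(n)),
                              site_position = 8L,
                              mod_type = "phosphorylation",
                              sequence = seqs,
                              label = "outside",
                              stringsAsFactors = FALSE),
         family = rep(seq_len(families), each = n_per_family),
         consensus = consensus)
}

#' Generate a synthetic complete index set
#'
#' Synthetic property scales (values standard-normal per residue,
#' accessions `SYNTHnnnn`) for width checks and planted-signal
#' experiments; any complete AAindex set can be substituted.
#'
#' @param n Number of scales.
#' @param seed Integer seed.
#' @return Named list of [AminoAcidIndex-class] objects.
#' @export
syntheticIndexSet <- function(n = 102L, seed = 1L) {
    withr::with_seed(as.integer(seed), {
        out <- lapply(seq_len(n), function(i) {
            new("AminoAcidIndex",
                accession = sprintf("SYNTH%04d", i),
                description = sprintf("synthetic property scale %d", i),
                values = stats::setNames(stats::rnorm(20L), .AA),
                category = NA_character_)
        })
    })
    names(out) <- vapply(out, accession, character(1))
    out
}
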