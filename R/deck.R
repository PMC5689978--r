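# MCNP-style input deck emission and validation.
#
# The computational model is a rectangular lattice (LAT=1) whose element size
# equals the CT voxel size and whose outer dimensions coincide with the CT
# volume, so the lattice element count equals the CT voxel count. Each
# distinct (tissue row, density) pair present in the material model becomes
# one lattice universe holding a cell of that material at that density
# (densities are carried on cell entries, negative g/cm3; material cards
# carry negative mass fractions per the MCNP convention). The FILL array is
# written x fastest, then y, then z, using the repeat notation `v nR`.
# Tallies follow the benchmark design: an F6 photon heating tally (collisional
# kerma to medium in medium over the full model) and an FMESH4 photon-fluence
# mesh tally restricted to the dose-grid extent, weighted by water mass
# energy-absorption coefficients (water kerma in medium). The phase-space
# source is referenced as a sidecar file plus the per-dwell transform table;
# no variance-reduction cards are emitted.

ELEMENT_ZAID <- c(H = 1000, C = 6000, N = 7000, O = 8000, Na = 11000,
                  Mg = 12000, P = 15000, S = 16000, Cl = 17000, Ar = 18000,
                  K = 19000, Ca = 20000)

#' Material cards for the tissues present in a model
#'
#' One card per distinct tissue row present; mass fractions are
#' negative-signed, densities live on the cell/lattice entries.
#'
#' @param model A `material_model` from [build_material_model()].
#' @return Character vector of card lines.
#' @export
build_materials <- function(model) {
  present <- sort(unique(as.vector(model$material_index)))
  tb <- model$tissue_table
  unlist(lapply(seq_along(present), function(k) {
    row <- present[k]
    fr <- tb$fractions[row, ]
    fr <- fr[fr > 0]
    zaid <- ELEMENT_ZAID[names(fr)]
    entries <- sprintf("%d -%.6f", zaid, fr)
    wrap_card(c(sprintf("m%d", k), entries),
              comment = sprintf("c material %d: %s", k, tb$table$name[row]))
  }))
}

# wrap card tokens to <= 80 columns with 5-space continuation
wrap_card <- function(tokens, comment = NULL) {
  lines <- character(0)
  cur <- tokens[1]
  for (tok in tokens[-1]) {
    if (nchar(cur) + 1 + nchar(tok) > 78) {
      lines <- c(lines, cur)
      cur <- paste0("     ", tok)
    } else cur <- paste(cur, tok)
  }
  lines <- c(lines, cur)
  if (!is.null(comment)) lines <- c(comment, lines)
  lines
}

#' Write an MCNP-style input deck
#'
#' @param model A `material_model`.
#' @param plan A [plan_model()] sharing the model's frame.
#' @param transforms Per-dwell transforms ([plan_transforms()]).
#' @param sampling A [sampling_table()].
#' @param dose_grid_extent List with `origin`, `spacing`, `dims` describing
#'   the DICOM RT dose grid the mesh tally should cover; `NULL` covers the
#'   whole model.
#' @param nps Number of histories (normally the phase-space record count).
#' @param phsp_file,transform_csv Sidecar file names referenced from the deck.
#' @param muen Data frame `energy_mev`, `muen_over_rho`; default the shipped
#'   water table.
#' @param title Deck title line.
#' @return An object of class `mc_deck`: blocks, manifest, and full `text`.
#' @export
write_deck <- function(model, plan, transforms, sampling,
                       dose_grid_extent = NULL, nps = NULL,
                       phsp_file = "source.phsp",
                       transform_csv = "transforms.csv",
                       muen = NULL, title = "brachydeck lattice model") {
  if (length(transforms) != nrow(plan$dwells))
    stop("transform count does not match dwell count")
  if (length(sampling$p) != nrow(plan$dwells))
    stop("sampling table does not match dwell count")
  if (is.null(muen)) muen <- utils::read.csv(extdata("muen_water.csv"))
  if (any(diff(muen$energy_mev) <= 0) || any(muen$muen_over_rho <= 0))
    stop("mu_en table must have strictly increasing energies and positive values")
  d <- dim(model$density)
  # one universe per distinct (tissue, density) pair
  dens_u <- sort(unique(as.vector(model$density)))
  di <- findInterval(as.vector(model$density), dens_u)
  code <- as.vector(model$material_index) * 1000L + di
  code_u <- sort(unique(code))
  uni <- match(code, code_u) + 1L   # universes 2..K+1 (1 is the lattice)
  mat_of_u <- (code_u %/% 1000L)
  den_of_u <- dens_u[code_u %% 1000L]
  present <- sort(unique(as.vector(model$material_index)))
  mat_card_of_u <- match(mat_of_u, present)

  ext_lo <- model$origin - model$spacing / 2
  ext_hi <- model$origin + (d - 0.5) * model$spacing

  ## cell block
  cells <- c(
    "c cell block",
    sprintf("1 0 -1 fill=1 imp:p=1"),
    "c lattice: element size equals the CT voxel size; FILL order is",
    "c x fastest, then y, then z (one entry per CT voxel)",
    wrap_card(c(sprintf("2 0 -2 lat=1 u=1 imp:p=1"),
                sprintf("fill=0:%d 0:%d 0:%d", d[1] - 1, d[2] - 1, d[3] - 1))))
  fill_lines <- encode_fill(uni)
  ucells <- vapply(seq_along(code_u), function(k) {
    sprintf("%d %d -%.4g -99 u=%d imp:p=1",
            10 + k, mat_card_of_u[k], den_of_u[k], k + 1L)
  }, character(1))
  cells <- c(cells, fill_lines, "c material universes", ucells,
             "999 0 1 imp:p=0")

  ## surface block
  mm2cm <- 0.1
  surfaces <- c(
    "c surface block (cm)",
    sprintf("1 rpp %.5f %.5f %.5f %.5f %.5f %.5f",
            ext_lo[1] * mm2cm, ext_hi[1] * mm2cm, ext_lo[2] * mm2cm,
            ext_hi[2] * mm2cm, ext_lo[3] * mm2cm, ext_hi[3] * mm2cm),
    sprintf("2 rpp 0 %.5f 0 %.5f 0 %.5f",
            model$spacing[1] * mm2cm, model$spacing[2] * mm2cm,
            model$spacing[3] * mm2cm),
    "99 so 1e5")

  ## data block
  if (is.null(nps)) nps <- 1e6
  if (is.null(dose_grid_extent))
    dose_grid_extent <- list(origin = model$origin, spacing = model$spacing,
                             dims = d)
  ge <- dose_grid_extent
  g_lo <- (ge$origin - ge$spacing / 2) * mm2cm
  g_hi <- (ge$origin + (ge$dims - 0.5) * ge$spacing) * mm2cm
  data_blk <- c(
    "c data block",
    "mode p",
    build_materials(model),
    "c collisional kerma to medium in medium over the full lattice",
    "f6:p 2",
    "c photon energy fluence mesh over the RT dose grid extent,",
    "c weighted to water kerma by mass energy-absorption coefficients",
    wrap_card(c("fmesh4:p geom=xyz",
                sprintf("origin=%.5f %.5f %.5f", g_lo[1], g_lo[2], g_lo[3]),
                sprintf("imesh=%.5f iints=%d", g_hi[1], ge$dims[1]),
                sprintf("jmesh=%.5f jints=%d", g_hi[2], ge$dims[2]),
                sprintf("kmesh=%.5f kints=%d", g_hi[3], ge$dims[3]))),
    wrap_card(c("de4", sprintf("%.6g", muen$energy_mev))),
    wrap_card(c("df4", sprintf("%.6g", muen$muen_over_rho))),
    "c phase-space source sidecar convention: photon records are read from",
    sprintf("c   file=%s (PHSP1 header + float32 E,x,y,z,u,v,w records)", phsp_file),
    sprintf("c   per-dwell transforms and sampling probabilities: %s", transform_csv),
    "c   each photon is placed by a transform drawn from the dwell-time",
    "c   probability distribution (fraction of dwell time to total time)",
    "c no variance reduction",
    sprintf("nps %d", as.integer(nps)))

  manifest <- list(
    n_lattice_elements = prod(d),
    lattice_dims = d,
    n_materials = length(present),
    n_universes = length(code_u),
    tally_ids = c("f6", "fmesh4"),
    nps = as.integer(nps))
  deck <- structure(list(
    title = title,
    cell_block = paste(cells, collapse = "\n"),
    surface_block = paste(surfaces, collapse = "\n"),
    data_block = paste(data_blk, collapse = "\n"),
    manifest = manifest), class = "mc_deck")
  deck
}

# run-length encode the universe vector into FILL continuation lines
encode_fill <- function(uni) {
  rl <- rle(uni)
  entries <- ifelse(rl$lengths == 1L, as.character(rl$values),
                    sprintf("%d %dR", rl$values, rl$lengths - 1L))
  # pack entries into continuation lines of at most 78 characters
  n <- length(entries)
  per_line <- 6L
  idx <- ceiling(seq_len(n) / per_line)
  vapply(split(entries, idx), function(e)
    paste0("     ", paste(e, collapse = " ")), character(1),
    USE.NAMES = FALSE)
}

#' Deck text
#' @param deck An `mc_deck`.
#' @return The complete deck as one string (three blocks separated by blank
#'   lines).
#' @export
deck_text <- function(deck) {
  paste(c(deck$title, deck$cell_block, "", deck$surface_block, "",
          deck$data_block, ""), collapse = "\n")
}

#' @export
print.mc_deck <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<mc_deck> %d lattice elements (%dx%dx%d), %d materials, %d universes\n",
              m$n_lattice_elements, m$lattice_dims[1], m$lattice_dims[2],
              m$lattice_dims[3], m$n_materials, m$n_universes))
  invisible(x)
}

#' Write a deck and its sidecars to a directory
#'
#' @param deck An `mc_deck`.
#' @param directory Output directory.
#' @param name Base name for the `.inp` file.
#' @return Path of the written deck file.
#' @export
save_deck <- function(deck, directory, name = "model") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(directory, paste0(name, ".inp"))
  writeLines(deck_text(deck), path, sep = "")
  path
}

#' Parse and validate an MCNP-style deck
#'
#' Splits the deck into its three blocks, expands the FILL repeat notation,
#' counts lattice entries, materials and tallies, and verifies mass-fraction
#' sums and lattice dimensions.
#'
#' @param text Deck text (single string or character vector of lines).
#' @return The reconstructed manifest (list), or an error describing the
#'   structural defect.
#' @export
validate_deck <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else text
  if (length(lines) < 2L) stop("deck too short")
  body <- lines[-1L]  # drop title
  blank <- which(body == "")
  if (length(blank) < 2L)
    stop("deck must contain three blocks separated by blank lines")
  cell <- body[seq_len(blank[1] - 1L)]
  surf <- body[(blank[1] + 1L):(blank[2] - 1L)]
  data_blk <- if (blank[2] + 1L <= length(body))
    body[(blank[2] + 1L):length(body)] else character(0)
  data_blk <- data_blk[data_blk != ""]
  if (length(data_blk) == 0L) stop("structural error: empty data block")
  if (length(surf) == 0L) stop("structural error: empty surface block")

  # lattice dims from the fill=0:i 0:j 0:k specification
  lat_line <- grep("lat=1", cell, value = TRUE)
  if (length(lat_line) != 1L) stop("no lattice cell found")
  fl <- grep("fill=\\d+:", cell)
  if (length(fl) != 1L) stop("no fill specification found")
  m <- regmatches(cell[fl],
                  regexec("fill=(\\d+):(\\d+) (\\d+):(\\d+) (\\d+):(\\d+)",
                          cell[fl]))[[1]]
  if (length(m) != 7L) stop("malformed fill range")
  dims <- c(as.integer(m[3]) - as.integer(m[2]) + 1L,
            as.integer(m[5]) - as.integer(m[4]) + 1L,
            as.integer(m[7]) - as.integer(m[6]) + 1L)
  # fill entries: the continuation lines (5-space indent) after the fill line
  i <- fl + 1L
  count <- 0
  max_u <- 0L
  while (i <= length(cell) && startsWith(cell[i], "     ")) {
    toks <- strsplit(trimws(cell[i]), " +")[[1]]
    reps <- grepl("R$", toks)
    plain <- suppressWarnings(as.integer(toks[!reps]))
    if (anyNA(plain)) stop("malformed fill entry")
    count <- count + sum(!reps) +
      sum(as.numeric(sub("R$", "", toks[reps])))
    if (length(plain)) max_u <- max(max_u, plain)
    i <- i + 1L
  }
  if (count != prod(dims))
    stop(sprintf(
      "lattice dimension mismatch: fill declares %d x %d x %d = %.0f elements but %.0f entries found",
      dims[1], dims[2], dims[3], prod(dims), count))

  # universes referenced in fill must exist as cells
  u_defined <- unique(as.integer(
    sub(".*u=(\\d+).*", "\\1", grep(" u=\\d+", cell, value = TRUE))))
  if (max_u > 1L && length(setdiff(seq(2L, max_u), u_defined)) > 0L)
    stop("fill references an undefined universe")

  # materials: m<k> cards with continuations; fractions sum to -1
  mstart <- grep("^m\\d+ ", data_blk)
  n_mat <- length(mstart)
  if (n_mat == 0L) stop("structural error: no material cards")
  for (s in mstart) {
    toks <- strsplit(trimws(data_blk[s]), " +")[[1]][-1]
    j <- s + 1L
    while (j <= length(data_blk) && startsWith(data_blk[j], "     ")) {
      toks <- c(toks, strsplit(trimws(data_blk[j]), " +")[[1]])
      j <- j + 1L
    }
    fr <- as.numeric(toks[seq(2, length(toks), by = 2)])
    if (abs(sum(fr) + 1) > 1e-6)
      stop(sprintf("material card %s mass fractions sum to %.8f, expected -1",
                   strsplit(data_blk[s], " ")[[1]][1], sum(fr)))
  }
  tally_ids <- character(0)
  if (any(grepl("^f6:p", data_blk))) tally_ids <- c(tally_ids, "f6")
  if (any(grepl("^fmesh4:p", data_blk))) tally_ids <- c(tally_ids, "fmesh4")
  nps_line <- grep("^nps ", data_blk, value = TRUE)
  nps <- if (length(nps_line)) as.integer(strsplit(nps_line[1], " +")[[1]][2])
         else NA_integer_
  list(n_lattice_elements = count, lattice_dims = dims,
       n_materials = n_mat,
       n_universes = length(setdiff(u_defined, 1L)),
       tally_ids = tally_ids, nps = nps)
}
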