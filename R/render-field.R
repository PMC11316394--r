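#' Specify the geometry and count budget of a rendered analysis field
#'
#' @param widthPx,heightPx field size in pixels (default 256 x 256).
#' @param pixelSizeUm pixel edge, um (default 0.1; resolves 1-2 um rods
#'   with >= 10 px of length).
#' @param countsC expected total carbon-bearing ion counts (12C2- +
#'   12C13C-) per cell.
#' @param countsN expected total nitrogen-bearing ion counts per cell.
#' @param countsS expected total 32S- counts per cell.
#' @param background expected background counts per pixel per channel,
#'   applied outside cell regions only.
#' @return list of field parameters for [renderSipField()].
#' @export
fieldSpec <- function(widthPx = 256L, heightPx = 256L, pixelSizeUm = 0.1,
                      countsC = 1e5, countsN = 2e4, countsS = 5e3,
                      background = 0.02) {
  stopifnot(widthPx >= 8, heightPx >= 8, pixelSizeUm > 0,
            countsC > 0, countsN > 0, countsS >= 0, background >= 0)
  list(widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
       pixelSizeUm = pixelSizeUm, countsC = countsC, countsN = countsN,
       countsS = countsS, background = background)
}

# Internal: pixel footprint of one cell. Algae are disks (diameter =
# true_length_um), bacteria rods (length x 0.5 um width) at a given angle.
.cellPixels <- function(partner, lengthUm, cxPx, cyPx, angle, pxUm, dims) {
  if (partner == "alga") {
    rPx <- (lengthUm / 2) / pxUm
    ext <- ceiling(rPx)
    xr <- max(1, floor(cxPx - ext)):min(dims[1], ceiling(cxPx + ext))
    yr <- max(1, floor(cyPx - ext)):min(dims[2], ceiling(cyPx + ext))
    g <- expand.grid(x = xr, y = yr)
    keep <- (g$x - cxPx)^2 + (g$y - cyPx)^2 <= rPx^2
    g[keep, , drop = FALSE]
  } else {
    halfL <- (lengthUm / 2) / pxUm
    halfW <- (0.5 / 2) / pxUm
    ext <- ceiling(sqrt(halfL^2 + halfW^2)) + 1
    xr <- max(1, floor(cxPx - ext)):min(dims[1], ceiling(cxPx + ext))
    yr <- max(1, floor(cyPx - ext)):min(dims[2], ceiling(cyPx + ext))
    g <- expand.grid(x = xr, y = yr)
    dx <- g$x - cxPx; dy <- g$y - cyPx
    u <- dx * cos(angle) + dy * sin(angle)     # along-axis
    v <- -dx * sin(angle) + dy * cos(angle)    # across-axis
    # capsule: rectangle with hemispherical caps
    du <- pmax(abs(u) - (halfL - halfW), 0)
    keep <- du^2 + v^2 <= halfW^2
    g[keep, , drop = FALSE]
  }
}

#' Render a synthetic nanoSIMS-style ion image field
#'
#' Draws each truth-table cell into a multi-channel Poisson count field:
#' algae as disks (diameter = `true_length_um`), bacteria as 0.5 um-wide
#' rods of their true length, at jittered grid positions (or at explicit
#' `x_um`/`y_um` positions if the truth table carries them). Per-pixel
#' channel expectations are partitioned by the cell's true atom fractions
#' under the random-pairing dimer model: 12C2- : 12C13C- as
#' `(1-p)^2 : 2p(1-p)` and 12C14N- : 12C15N- as `(1-q) : q`. Counts are
#' independent Poisson draws; background (outside cells) is near zero.
#'
#' @param truth data.frame with columns `cell_id`, `partner`,
#'   `true_p13C`, `true_p15N`, `true_length_um` (e.g. a subset of
#'   [simulateCoculture()]'s truth table), optionally `x_um`/`y_um`
#'   positions and annotation columns `culture`, `replicate`,
#'   `timepoint_h`.
#' @param spec field geometry and count budget from [fieldSpec()].
#' @param seed integer seed for placement jitter and Poisson draws.
#' @param fieldId identifier stamped on the stack.
#' @return list with `stack` ([IonImageStack-class]) and `rois`
#'   ([ROISet-class]); mask labels are the row indices of `truth`.
#' @examples
#' tr <- data.frame(cell_id = "c1", partner = "bacterium",
#'                  true_p13C = 0.05, true_p15N = 0.01, true_length_um = 2)
#' f <- renderSipField(tr, fieldSpec(widthPx = 64, heightPx = 64), seed = 1)
#' @export
renderSipField <- function(truth, spec = fieldSpec(), seed = 1L,
                           fieldId = "field1") {
  stopifnot(nrow(truth) >= 1)
  need <- c("cell_id", "partner", "true_p13C", "true_p15N", "true_length_um")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(truth$true_p13C < 0 | truth$true_p13C > 1 |
          truth$true_p15N < 0 | truth$true_p15N > 1))
    stop("true atom fractions must be in [0, 1]")
  if (any(truth$true_length_um <= 0)) stop("cell lengths must be positive")
  dims <- c(spec$widthPx, spec$heightPx)
  pxUm <- spec$pixelSizeUm

  .withSeed(seed, {
    n <- nrow(truth)
    extPx <- ifelse(truth$partner == "alga",
                    truth$true_length_um / pxUm,
                    truth$true_length_um / pxUm) + 4
    explicit <- all(c("x_um", "y_um") %in% names(truth))
    if (explicit) {
      cx <- truth$x_um / pxUm; cy <- truth$y_um / pxUm
    } else {
      # jittered grid: pitch fits the largest cell
      pitch <- max(extPx) + 2
      ncol_ <- floor(dims[1] / pitch); nrow_ <- floor(dims[2] / pitch)
      if (ncol_ * nrow_ < n)
        stop(sprintf(paste0("field (%d x %d px) cannot hold %d cells at ",
                            "pitch %.0f px; enlarge the field or split cells ",
                            "across fields"), dims[1], dims[2], n, pitch))
      slots <- sample(ncol_ * nrow_, n)
      cx <- ((slots - 1) %% ncol_) * pitch + pitch / 2 +
        stats::runif(n, -1, 1)
      cy <- ((slots - 1) %/% ncol_) * pitch + pitch / 2 +
        stats::runif(n, -1, 1)
    }
    angle <- stats::runif(n, 0, pi)

    mask <- matrix(0L, dims[1], dims[2])
    pixList <- vector("list", n)
    for (i in seq_len(n)) {
      px <- .cellPixels(truth$partner[i], truth$true_length_um[i],
                        cx[i], cy[i], angle[i], pxUm, dims)
      if (nrow(px) == 0L)
        stop("cell ", truth$cell_id[i], " fell entirely outside the field")
      idx <- cbind(px$x, px$y)
      clash <- mask[idx] != 0L
      if (any(clash)) {
        other <- unique(truth$cell_id[mask[idx][clash]])
        stop("overlapping cells: ", truth$cell_id[i], " collides with ",
             paste(other, collapse = ", "))
      }
      mask[idx] <- i
      pixList[[i]] <- idx
    }

    ch <- lapply(c("C2", "C13C", "CN", "C15N", "S"), function(nm) {
      lam <- matrix(spec$background, dims[1], dims[2])
      lam[mask != 0L] <- 0   # background outside cells only
      lam
    })
    names(ch) <- c("C2", "C13C", "CN", "C15N", "S")
    for (i in seq_len(n)) {
      idx <- pixList[[i]]
      area <- nrow(idx)
      p <- truth$true_p13C[i]; q <- truth$true_p15N[i]
      lamC <- spec$countsC / area
      lamN <- spec$countsN / area
      ch$C2[idx] <- lamC * (1 - p)^2
      ch$C13C[idx] <- lamC * 2 * p * (1 - p)
      ch$CN[idx] <- lamN * (1 - q)
      ch$C15N[idx] <- lamN * q
      ch$S[idx] <- spec$countsS / area
    }
    ch <- lapply(ch, function(lam) {
      m <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      storage.mode(m) <- "integer"
      m
    })

    tp <- if ("timepoint_h" %in% names(truth)) truth$timepoint_h else NA_real_
    ann <- data.frame(
      label = seq_len(n),
      cell_id = truth$cell_id,
      partner = truth$partner,
      culture = if ("culture" %in% names(truth)) truth$culture else "culture1",
      replicate = if ("replicate" %in% names(truth)) truth$replicate else 1L,
      timepoint_h = tp
    )
    stack <- IonImageStack(ch, pixelSizeUm = pxUm, fieldId = fieldId,
                           cultureId = as.character(ann$culture[1]),
                           timepointH = tp[1])
    list(stack = stack, rois = ROISet(mask, ann))
  })
}

#' Write / read an ion image stack as per-channel TIFF files
#'
#' Counts are stored losslessly as 16-bit TIFF (integer counts scaled by
#' 65535 on write and recovered exactly on read); per-pixel ion counts far
#' exceeding 16 bits are refused. One file per channel,
#' `<prefix>_<channel>.tif`, plus `<prefix>_meta.yaml` with the pixel size
#' and acquisition metadata.
#'
#' @param stack an [IonImageStack-class].
#' @param prefix path prefix for the output files.
#' @return `writeIonImageStack()`: invisibly, the files written;
#'   `readIonImageStack()`: the reconstructed [IonImageStack-class].
#' @export
writeIonImageStack <- function(stack, prefix) {
  files <- character()
  for (nm in channelNames(stack)) {
    m <- ionCounts(stack, nm)
    if (any(m > 65535L))
      stop("channel ", nm, " has per-pixel counts above 65535; ",
           "16-bit storage would be lossy")
    f <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF(m / 65535, f, bits.per.sample = 16L, compression = "none")
    files <- c(files, f)
  }
  meta <- list(pixel_size_um = pixelSize(stack), field_id = stack@fieldId,
               culture_id = stack@cultureId, timepoint_h = stack@timepointH,
               channels = channelNames(stack))
  mf <- paste0(prefix, "_meta.yaml")
  yaml::write_yaml(meta, mf)
  invisible(c(files, mf))
}

#' @rdname writeIonImageStack
#' @export
readIonImageStack <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  ch <- lapply(meta$channels, function(nm) {
    m <- tiff::readTIFF(paste0(prefix, "_", nm, ".tif"))
    mi <- round(m * 65535)
    storage.mode(mi) <- "integer"
    mi
  })
  names(ch) <- meta$channels
  IonImageStack(ch, pixelSizeUm = meta$pixel_size_um, fieldId = meta$field_id,
                cultureId = meta$culture_id,
                timepointH = if (is.null(meta$timepoint_h)) NA_real_
                             else meta$timepoint_h)
}

#' Write / read an ROI label mask (16-bit TIFF) with its annotation CSV
#'
#' @param rois an [ROISet-class].
#' @param prefix path prefix; writes `<prefix>_mask.tif` and
#'   `<prefix>_rois.csv`.
#' @return `writeRoiSet()`: invisibly, the files; `readRoiSet()`: the
#'   [ROISet-class].
#' @export
writeRoiSet <- function(rois, prefix) {
  m <- roiMask(rois)
  if (any(m > 65535L)) stop("more than 65535 labels cannot be stored in 16 bits")
  f1 <- paste0(prefix, "_mask.tif")
  tiff::writeTIFF(m / 65535, f1, bits.per.sample = 16L, compression = "none")
  f2 <- paste0(prefix, "_rois.csv")
  utils::write.csv(roiAnnotations(rois), f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' @rdname writeRoiSet
#' @export
readRoiSet <- function(prefix) {
  m <- round(tiff::readTIFF(paste0(prefix, "_mask.tif")) * 65535)
  storage.mode(m) <- "integer"
  ann <- utils::read.csv(paste0(prefix, "_rois.csv"))
  ROISet(m, ann)
}
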