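#' Channel role map
#'
#' Declares what each channel in a stack is: the genetically encoded terminal
#' reporter (e.g. Synaptophysin-YFP/mCherry), the nuclear stain (DAPI), an
#' antibody stain, or a FISH probe. The role map, not the TIFF metadata, is
#' the source of truth for channel identity and order.
#'
#' @param channel Character vector of unique channel names.
#' @param role Character vector, one of `"terminal_reporter"`, `"nuclear"`,
#'   `"antibody"`, `"fish_probe"`, `"other"`; recycled if length 1.
#' @param meta Optional character vector of free-form acquisition metadata.
#' @return A tibble of class `channel_roles` with columns `channel`, `role`,
#'   `meta`.
#' @examples
#' channel_roles(
#'   c("YFP", "DAPI", "VGAT", "VAChT"),
#'   c("terminal_reporter", "nuclear", "antibody", "antibody")
#' )
#' @export
channel_roles <- function(channel, role, meta = NA_character_) {
  stopifnot(is.character(channel), length(channel) >= 1)
  if (anyDuplicated(channel)) {
    stop("channel names must be unique", call. = FALSE)
  }
  allowed <- c("terminal_reporter", "nuclear", "antibody", "fish_probe", "other")
  role <- rep_len(role, length(channel))
  bad <- setdiff(unique(role), allowed)
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(role == "nuclear") > 1) {
    stop("at most one nuclear channel per run", call. = FALSE)
  }
  out <- tibble::tibble(
    channel = channel,
    role = role,
    meta = rep_len(meta, length(channel))
  )
  class(out) <- c("channel_roles", class(out))
  out
}

#' Multi-channel 3D image stack
#'
#' The common carrier for all imaging stages: a set of named channels, each a
#' 3D numeric array indexed `[z, row, col]` (1-based), plus voxel dimensions
#' in nanometres and the channel role map. Array-tomography ribbons are cut
#' at 70 nm, so the default z voxel size is 70 nm.
#'
#' @param channels Named list of 3D numeric arrays, all the same dimension.
#'   Plain matrices are promoted to single-plane arrays.
#' @param roles A [channel_roles()] table covering every channel, or `NULL`
#'   to mark all channels `"other"`.
#' @param voxel_size_nm Numeric length-3 `(z, y, x)` voxel size in nm.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(channels, roles = NULL, voxel_size_nm = c(70, 100, 100)) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || anyDuplicated(names(channels))) {
    stop("channels must be uniquely named", call. = FALSE)
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(1, dim(ch)))
    if (!is.array(ch) || length(dim(ch)) != 3 || !is.numeric(ch)) {
      stop("each channel must be a numeric 3D array", call. = FALSE)
    }
    ch
  })
  dims <- vapply(channels, dim, integer(3))
  if (any(dims != dims[, 1])) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  if (is.null(roles)) {
    roles <- channel_roles(names(channels), "other")
  }
  missing_roles <- setdiff(names(channels), roles$channel)
  if (length(missing_roles) > 0) {
    stop(
      "channels without a declared role: ",
      paste(missing_roles, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      channels = channels,
      roles = roles,
      voxel_size_nm = stats::setNames(as.numeric(voxel_size_nm), c("z", "y", "x")),
      normalized = stats::setNames(
        rep(FALSE, length(channels)), names(channels)
      )
    ),
    class = "volume_stack"
  )
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(
    "<volume_stack> ", length(x$channels), " channel(s), ",
    d[1], " plane(s) of ", d[2], "x", d[3], " voxels\n",
    sep = ""
  )
  cat(
    " voxel size (z,y,x) nm:",
    paste(x$voxel_size_nm, collapse = ", "), "\n"
  )
  for (nm in names(x$channels)) {
    role <- x$roles$role[match(nm, x$roles$channel)]
    cat(
      sprintf(
        "  %-12s %-17s [%.4g, %.4g]%s\n", nm, role,
        min(x$channels[[nm]]), max(x$channels[[nm]]),
        if (isTRUE(x$normalized[[nm]])) " normalized" else ""
      )
    )
  }
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$channels[[1]])

#' Extract one channel of a stack
#'
#' @param stack A [volume_stack()].
#' @param channel Channel name.
#' @return The channel's 3D array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("no channel named '", channel, "'", call. = FALSE)
  }
  stack$channels[[channel]]
}

#' Names of channels holding a given role
#'
#' @param stack A [volume_stack()].
#' @param role A role string as in [channel_roles()].
#' @return Character vector (possibly empty).
#' @export
channels_with_role <- function(stack, role) {
  stack$roles$channel[stack$roles$role == role]
}

#' Read a multi-channel stack from a multi-page TIFF
#'
#' Pages are expected plane-major: all channels of z-plane 1 first (in role-map
#' order), then all channels of plane 2, and so on. The role map, not the file,
#' decides how many channels there are and what they are called.
#'
#' @param path Path to a multi-page TIFF.
#' @param roles A [channel_roles()] table; its row order is the within-plane
#'   page order.
#' @param voxel_size_nm Voxel size `(z, y, x)` in nm attached to the stack.
#' @return A [volume_stack()].
#' @export
read_stack <- function(path, roles, voxel_size_nm = c(70, 100, 100)) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  stopifnot(inherits(roles, "channel_roles"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- nrow(roles)
  if (length(pages) %% n_ch != 0) {
    stop(
      "page count (", length(pages), ") is not a multiple of the declared ",
      n_ch, " channels", call. = FALSE
    )
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # drop any extra sample dimension
    if (!is.numeric(p)) stop("non-numeric pixel data", call. = FALSE)
    p
  })
  nz <- length(pages) %/% n_ch
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  channels <- lapply(seq_len(n_ch), function(ci) {
    arr <- array(0, dim = c(nz, ny, nx))
    for (zi in seq_len(nz)) {
      arr[zi, , ] <- pages[[(zi - 1L) * n_ch + ci]]
    }
    arr
  })
  names(channels) <- roles$channel
  volume_stack(channels, roles = roles, voxel_size_nm = voxel_size_nm)
}

#' Write a stack to a multi-page TIFF
#'
#' Pages are written plane-major (see [read_stack()]) as 32-bit samples.
#' Values are clipped to `[0, 1]`; storage quantization is below 1e-9, so a
#' write/read round trip preserves voxel values to that tolerance.
#'
#' @param stack A [volume_stack()] with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack)
  pages <- vector("list", d[1] * length(stack$channels))
  k <- 1L
  for (zi in seq_len(d[1])) {
    for (nm in stack$roles$channel) {
      pages[[k]] <- pmin(pmax(stack$channels[[nm]][zi, , ], 0), 1)
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
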