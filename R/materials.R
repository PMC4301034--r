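#' @include AllClasses.R configs.R
NULL

#' Grayscale to Hounsfield units
#'
#' The 12-bit scanner grayscale maps linearly to the Hounsfield scale; the
#' default slope 1 / intercept -1024 is the conventional CT offset
#' (grayscale 1024 = 0 HU, grayscale 0 = -1024 HU).
#'
#' @param values numeric grayscale values in \eqn{[0, 4095]}.
#' @param model a \linkS4class{CalibrationModel}.
#' @return HU values, same shape.
#' @export
grayToHounsfield <- function(values, model = calibrationModel()) {
  if (any(values < 0 | values > GRAY_MAX))
    stop("grayscale values must lie in the 12-bit range")
  model@huSlope * values + model@huIntercept
}

#' Hounsfield units to apparent density
#'
#' Affine calibration line, in analogy to a densitometric calibration
#' phantom.  The default line puts the synthetic phantom's cancellous and
#' cortical gray levels at 0.5 and 1.8 g/cm^3.
#'
#' @param hu numeric HU values.
#' @inheritParams grayToHounsfield
#' @return apparent density in g/cm^3, floored at 0.
#' @export
hounsfieldToDensity <- function(hu, model = calibrationModel()) {
  pmax(model@rhoSlope * hu + model@rhoIntercept, 0)
}

#' Apparent density to Young's modulus by power law
#'
#' \eqn{E = a \rho^b} with \code{a} in MPa, returned in Pa.  Monotone
#' increasing in density; \eqn{\rho = 0} yields 0, which callers must floor
#' to \code{EMin} before meshing.
#'
#' @param rho apparent density, g/cm^3 (must be >= 0).
#' @inheritParams grayToHounsfield
#' @return Young's modulus in Pa, same shape.
#' @export
densityToModulus <- function(rho, model = calibrationModel()) {
  if (any(rho < 0)) stop("negative density rejected")
  model@powerA * 1e6 * rho^model@powerB
}

#' Assign per-voxel elastic constants
#'
#' Bone voxels (cancellous, cortical) receive the power-law modulus computed
#' from their (diffused) grayscale through the calibration chain, clamped to
#' \code{[EMin, ECortical]}; implant voxels receive the titanium constants
#' exactly; soft-tissue voxels receive the soft constants.  Nonunion-masked
#' voxels are then overridden by the scenario: \code{"worst_case"} sets them
#' all to soft tissue (no fusion anywhere), \code{"full_fusion"} sets them all
#' to cortical bone, and an explicit \code{fusedMask} sets masked cells to
#' cortical and the rest to soft tissue.
#'
#' @param labels a \linkS4class{LabelVolume} (segmented, nonunion marked for
#'   the two scenario overrides).
#' @param model a \linkS4class{CalibrationModel}.
#' @param scenario one of \code{"as_segmented"}, \code{"worst_case"},
#'   \code{"full_fusion"}, \code{"mask"}.
#' @param fusedMask 3D logical array (same shape) used when
#'   \code{scenario = "mask"}: TRUE = fused (cortical), FALSE = soft.
#' @return a \linkS4class{MaterialMap}.
#' @export
assignMaterials <- function(labels, model = calibrationModel(),
                            scenario = c("as_segmented", "worst_case",
                                         "full_fusion", "mask"),
                            fusedMask = NULL) {
  scenario <- match.arg(scenario)
  validObject(model)
  lab <- labels@labels
  E <- array(0, dim = dim(lab))
  nu <- array(model@nuBone, dim = dim(lab))

  bone <- lab == 2L | lab == 3L
  rho <- hounsfieldToDensity(grayToHounsfield(labels@grayscale[bone], model),
                             model)
  E[bone] <- pmin(pmax(densityToModulus(rho, model), model@EMin),
                  model@ECortical)
  E[lab == 1L] <- model@ESoft
  nu[lab == 1L] <- model@nuSoft
  E[lab == 4L] <- model@EImplant
  nu[lab == 4L] <- model@nuImplant

  nn <- labels@nonunion
  if (scenario == "worst_case") {
    E[nn] <- model@ESoft
    nu[nn] <- model@nuSoft
  } else if (scenario == "full_fusion") {
    E[nn] <- model@ECortical
    nu[nn] <- model@nuBone
  } else if (scenario == "mask") {
    if (is.null(fusedMask) || !identical(dim(fusedMask), dim(lab)))
      stop("scenario 'mask' needs a fusedMask with the label-volume shape")
    fused <- nn & fusedMask
    E[fused] <- model@ECortical
    nu[fused] <- model@nuBone
    unfused <- nn & !fusedMask
    E[unfused] <- model@ESoft
    nu[unfused] <- model@nuSoft
  }
  new("MaterialMap", E = E, nu = nu, labels = labels, scenario = scenario)
}
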