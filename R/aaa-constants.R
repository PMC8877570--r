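# Shared constants (defined first in collation order).

.COMPOUNDS <- c("HCQ", "DesCQ", "DesHCQ", "DiDesCQ")

.METABOLITES <- c("DesCQ", "DesHCQ", "DiDesCQ")

.THETA_NAMES <- c("lag", "ka", "v", "cl_parent",
                  "cl_form_DesCQ", "cl_form_DesHCQ", "cl_form_DiDesCQ",
                  "cl_met_DesCQ", "cl_met_DesHCQ", "cl_met_DiDesCQ")

.ETA_NAMES <- c("cl_parent", "v", "cl_met_DesCQ", "cl_met_DesHCQ",
                "cl_met_DiDesCQ")
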