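# Regenerates R/qed_constants.R from the published QED method constants
# (asymmetric-double-sigmoid parameters, descriptor weights, acceptor and
# structural-alert SMARTS) as distributed with the RDKit QED reference
# implementation. Run from the repository root:
#   python data-raw/make_qed_constants.py
from rdkit.Chem import QED

props = ["MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"]


def r_str(s):
    return '"' + s.replace("\\", "\\\\").replace('"', '\\"') + '"'


lines = []
lines.append("# Generated by data-raw/make_qed_constants.py -- do not edit.")
lines.append("# Published constants of the QED desirability-function method:")
lines.append("# asymmetric double sigmoid (ADS) parameters and descriptor")
lines.append("# weights from the original publication's supplementary data,")
lines.append("# plus the hydrogen-bond-acceptor SMARTS and the")
lines.append("# structural-alert SMARTS list of the same method.")
lines.append("")
lines.append(".QED_ADS <- list(")
rows = []
for p in props:
    a = QED.adsParameters[p]
    rows.append(
        "  %s = c(a = %.9g, b = %.9g, c = %.9g, d = %.9g, e = %.9g, "
        "f = %.9g, dmax = %.9g)" % (p, a.A, a.B, a.C, a.D, a.E, a.F, a.DMAX)
    )
lines.append(",\n".join(rows))
lines.append(")")
lines.append("")
w = QED.WEIGHT_MEAN
lines.append(
    ".QED_WEIGHTS_MEAN <- c(%s)"
    % ", ".join("%s = %.9g" % (p, getattr(w, p)) for p in props)
)
w = QED.WEIGHT_MAX
lines.append(
    ".QED_WEIGHTS_MAX <- c(%s)"
    % ", ".join("%s = %.9g" % (p, getattr(w, p)) for p in props)
)
lines.append("")
lines.append(".QED_ACCEPTOR_SMARTS <- c(")
lines.append(",\n".join("  " + r_str(s) for s in QED.AcceptorSmarts))
lines.append(")")
lines.append("")
lines.append(".QED_ALERT_SMARTS <- c(")
lines.append(",\n".join("  " + r_str(s) for s in QED.StructuralAlertSmarts))
lines.append(")")
lines.append("")

with open("R/qed_constants.R", "w") as fh:
    fh.write("\n".join(lines))
print("wrote R/qed_constants.R with", len(QED.StructuralAlertSmarts), "alerts")
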