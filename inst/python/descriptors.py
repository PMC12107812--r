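"""Batched molecular descriptors: QED and synthetic accessibility.

Reads SMILES, one per line, on stdin; writes tab-separated lines
``smiles<TAB>qed<TAB>sa_score`` on stdout (NA fields for molecules that
fail to parse).  Uses RDKit's QED (default weights) and the
fragment-contribution synthetic accessibility scorer shipped in RDKit's
Contrib tree.
"""
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, RDConfig

RDLogger.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def main():
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            print("%s\tNA\tNA" % smi)
            continue
        try:
            q = QED.qed(mol)
            sa = sascorer.calculateScore(mol)
            print("%s\t%.6f\t%.6f" % (smi, q, sa))
        except Exception:
            print("%s\tNA\tNA" % smi)


if __name__ == "__main__":
    main()
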