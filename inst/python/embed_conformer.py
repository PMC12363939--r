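"""Conformer embedding / energy backend (RDKit).

Called by the R package as a subprocess:

  python embed_conformer.py embed  <in.mol> <out.json> <seed> <max_iter>
  python embed_conformer.py energy <in.mol> <out.json>

`embed` reads a MOL block (atom order is preserved throughout), assigns
stereo descriptors from the input coordinates when present, re-embeds the
molecule from the graph with ETKDG at the given random seed, minimizes with
MMFF94 (UFF when MMFF94 parameters are missing) and reports energies in
kcal/mol plus the final coordinates. `energy` computes a single-point
force-field energy for the coordinates in the MOL block.
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def load(path):
    with open(path) as fh:
        block = fh.read()
    mol = Chem.MolFromMolBlock(block, removeHs=False, sanitize=True)
    if mol is None:
        raise ValueError("RDKit could not parse the MOL block")
    return mol


def forcefield(mol):
    if AllChem.MMFFHasAllMoleculeParams(mol):
        props = AllChem.MMFFGetMoleculeProperties(mol)
        return AllChem.MMFFGetMoleculeForceField(mol, props), "MMFF94"
    return AllChem.UFFGetMoleculeForceField(mol), "UFF"


def has_coords(mol):
    conf = mol.GetConformer() if mol.GetNumConformers() else None
    if conf is None:
        return False
    pos = conf.GetPositions()
    return float(abs(pos).max()) > 1e-6


def cmd_embed(mol_path, out_path, seed, max_iter):
    mol = load(mol_path)
    n_input = mol.GetNumAtoms()
    if has_coords(mol):
        Chem.AssignStereochemistryFrom3D(mol)
    mol.RemoveAllConformers()
    if not any(a.GetAtomicNum() == 1 for a in mol.GetAtoms()):
        mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    cid = AllChem.EmbedMolecule(mol, params)
    if cid < 0:
        raise ValueError("ETKDG embedding failed")
    ff, ff_name = forcefield(mol)
    e_init = ff.CalcEnergy()
    status = ff.Minimize(maxIts=max_iter)
    e_final = ff.CalcEnergy()
    pos = mol.GetConformer().GetPositions()
    out = {
        "forcefield": ff_name,
        "initial_energy_kcal": e_init,
        "final_energy_kcal": e_final,
        "converged": status == 0,
        "n_input_atoms": n_input,
        "elements": [a.GetSymbol() for a in mol.GetAtoms()],
        "coords": [[float(v) for v in row] for row in pos],
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


def cmd_energy(mol_path, out_path):
    mol = load(mol_path)
    if not has_coords(mol):
        raise ValueError("energy mode needs coordinates in the MOL block")
    ff, ff_name = forcefield(mol)
    with open(out_path, "w") as fh:
        json.dump({"forcefield": ff_name, "energy_kcal": ff.CalcEnergy()}, fh)


def main(argv):
    if argv[0] == "embed":
        cmd_embed(argv[1], argv[2], int(argv[3]), int(argv[4]))
    elif argv[0] == "energy":
        cmd_energy(argv[1], argv[2])
    else:
        raise SystemExit("unknown mode " + argv[0])


if __name__ == "__main__":
    main(sys.argv[1:])
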