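"""Independent re-implementation of the package's circular fingerprint.

Reads "name\tsmiles\tn_bits\tradius" lines on stdin; for each, prints
"name\t<sorted comma-separated set bit indices>". Molecular perception
(hydrogen counts, valences, charges) comes from RDKit, independently of the
OpenBabel-based R implementation; the hashing spec is the one documented in
smiles_to_fingerprint(): per-atom invariant hash of (Z, heavy degree, H
count, formal charge, twice total valence), iteratively rehashed with
sorted neighbor invariants while the neighborhood ball still grows, folded
modulo n_bits. Kekulizing with cleared aromatic flags makes per-atom total
valences explicit; they are invariant across kekulizations (every aromatic
atom carries exactly one double bond in any Kekule structure, or an
exocyclic one), which is what makes cross-toolkit agreement possible.
"""
import sys

from rdkit import Chem

MOD = 2147483647
MULT = 1000003


def hash_ints(xs):
    h = 17
    for x in xs:
        h = (h * MULT + (x + 128)) % MOD
    return h


def fingerprint_bits(smiles, n_bits, radius):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparseable SMILES: " + smiles)
    Chem.Kekulize(mol, clearAromaticFlags=True)
    atoms = list(mol.GetAtoms())
    neighbors = []
    inv = []
    for a in atoms:
        heavy = [n.GetIdx() for n in a.GetNeighbors() if n.GetAtomicNum() > 1]
        nh = a.GetTotalNumHs(includeNeighbors=True)
        # GetBondTypeAsDouble after kekulization is integral (1, 2, 3)
        valence2 = 2 * nh + sum(
            int(round(2 * b.GetBondTypeAsDouble()))
            for b in a.GetBonds()
            if b.GetOtherAtom(a).GetAtomicNum() > 1
        )
        neighbors.append(heavy)
        inv.append(
            hash_ints(
                [a.GetAtomicNum(), len(heavy), nh, a.GetFormalCharge(),
                 valence2]
            )
        )
    ids = list(inv)
    ball = [{i} for i in range(len(atoms))]
    for r in range(1, radius + 1):
        inv_new = [
            hash_ints([r, inv[i]] + sorted(inv[j] for j in neighbors[i]))
            for i in range(len(atoms))
        ]
        ball_new = [
            ball[i].union(*[ball[j] for j in neighbors[i]])
            if neighbors[i] else set(ball[i])
            for i in range(len(atoms))
        ]
        for i in range(len(atoms)):
            if len(ball_new[i]) > len(ball[i]):
                ids.append(inv_new[i])
        inv = inv_new
        ball = ball_new
    return sorted({i % n_bits for i in ids})


def main():
    for line in sys.stdin:
        line = line.rstrip("\n")
        if not line:
            continue
        name, smiles, n_bits, radius = line.split("\t")
        bits = fingerprint_bits(smiles, int(n_bits), int(radius))
        sys.stdout.write(name + "\t" + ",".join(map(str, bits)) + "\n")


if __name__ == "__main__":
    main()
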