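#!/usr/bin/env python
"""Construct the idealized nucleotide / base-pair templates shipped under
inst/extdata/templates.

The templates are synthetic idealized geometry built from chemical
component dictionary residue geometry (via biotite) plus canonical helix
and pairing parameters:

* per-form (A / B) single-nucleotide templates in a base-pair frame whose
  helical symmetry operation (twist about z, rise along z) generates the
  duplex, with the second strand as the 180-degree rotation about y of the
  complementary template (exact dyad);
* Hoogsteen base-pair templates (A(syn)-T, A(syn)-U, G(syn)-C+,
  G(syn)-G(anti)) satisfying the standard Hoogsteen hydrogen-bond
  geometry and, for purine-pyrimidine pairs, a constricted C1'-C1'
  distance.

Run from the repository root:  python data-raw/make_templates.py
Only the emitted text files are used by the package at run time.
"""

import numpy as np
from scipy.optimize import least_squares
import biotite.structure.info as info

OUT = "inst/extdata/templates"

# ----------------------------------------------------------------- vectors


def unit(v):
    return v / np.linalg.norm(v)


def dihedral(p1, p2, p3, p4):
    b1, b2, b3 = p2 - p1, p3 - p2, p4 - p3
    n1, n2 = np.cross(b1, b2), np.cross(b2, b3)
    x = np.dot(n1, n2)
    y = np.dot(np.cross(n1, n2), unit(b2))
    return np.degrees(np.arctan2(y, x))


def angle(p1, p2, p3):
    u, v = unit(p1 - p2), unit(p3 - p2)
    return np.degrees(np.arccos(np.clip(np.dot(u, v), -1, 1)))


def nerf(a, b, c, r, theta, phi):
    th, ph = np.radians(theta), np.radians(phi)
    bc = unit(c - b)
    n = unit(np.cross(b - a, bc))
    m = np.cross(n, bc)
    d = np.array([-r * np.cos(th), r * np.sin(th) * np.cos(ph),
                  r * np.sin(th) * np.sin(ph)])
    return c + d[0] * bc + d[1] * m + d[2] * n


def rot_axis(axis, ang_deg):
    u = unit(axis)
    a = np.radians(ang_deg)
    K = np.array([[0, -u[2], u[1]], [u[2], 0, -u[0]], [-u[1], u[0], 0]])
    return np.eye(3) + np.sin(a) * K + (1 - np.cos(a)) * (K @ K)


# self-check NeRF conventions against the torsion definition
_a = np.array([1.0, 0, 0])
_b = np.array([0.0, 0, 0])
_c = np.array([0.0, 1.5, 0])
_p = nerf(_a, _b, _c, 1.4, 109.0, 57.0)
assert abs(dihedral(_a, _b, _c, _p) - 57.0) < 1e-8
assert abs(angle(_b, _c, _p) - 109.0) < 1e-8

# ------------------------------------------------------------- CCD geometry


def ccd(resname):
    r = info.residue(resname)
    r = r[r.element != "H"]
    return {n: c for n, c in zip(r.atom_name, r.coord)}


PUR_RING = ["N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"]
PYR_RING = ["N1", "C2", "N3", "C4", "C5", "C6"]
EXO = {"A": ["N6"], "G": ["O6", "N2"], "C": ["O2", "N4"],
       "U": ["O2", "O4"], "T": ["O2", "O4", "C7"]}


def base_letter(resname):
    return resname[-1]


def base_atom_names(resname):
    b = base_letter(resname)
    ring = PUR_RING if b in "AG" else PYR_RING
    return ring + EXO[b]


def glyco_n(resname):
    return "N9" if base_letter(resname) in "AG" else "N1"


def flat_base(resname):
    """Planar 2D base template: origin at glycosidic N, +x toward C1'.

    Returns dict atom -> (x, y) including C1', with a right-handed layout
    (the 'face-up' orientation used for the left/reference strand).
    """
    cc = ccd(resname)
    names = base_atom_names(resname) + ["C1'"]
    pts = np.array([cc[n] for n in names])
    center = pts.mean(axis=0)
    # best-fit plane via SVD
    u, s, vt = np.linalg.svd(pts - center)
    nrm = vt[2]
    proj = (pts - center) - np.outer((pts - center) @ nrm, nrm)
    # 2D frame: origin N, x toward C1'
    i_n = names.index(glyco_n(resname))
    i_c1 = names.index("C1'")
    o = proj[i_n]
    ex = unit(proj[i_c1] - o)
    ey = np.cross(nrm, ex)
    xy = np.column_stack([(proj - o) @ ex, (proj - o) @ ey])
    # fixed handedness so that the Watson-Crick edge faces the partner in
    # the pair frame: purines with C8 below the glycosidic axis,
    # pyrimidines with C2 above it
    if base_letter(resname) in "AG":
        if xy[names.index("C8"), 1] > 0:
            xy[:, 1] *= -1
    else:
        if xy[names.index("C2"), 1] < 0:
            xy[:, 1] *= -1
    return {n: xy[k] for k, n in enumerate(names)}


# --------------------------------------------------------------- sugar ring


def ring_torsion_targets(P, numax):
    return [numax * np.cos(np.radians(P + (j - 2) * 144.0))
            for j in range(5)]


def build_ring(P, numax, chem):
    """Five-membered sugar ring hitting the pseudorotation target.

    Returns dict with C1', C2', C3', C4', O4' coordinates.
    """
    cc = ccd("A" if chem == "ribo" else "DA")
    atoms = ["C1'", "C2'", "C3'", "C4'", "O4'"]
    bonds = [("C1'", "C2'"), ("C2'", "C3'"), ("C3'", "C4'"),
             ("C4'", "O4'"), ("O4'", "C1'")]
    angs = [("O4'", "C1'", "C2'"), ("C1'", "C2'", "C3'"),
            ("C2'", "C3'", "C4'"), ("C3'", "C4'", "O4'"),
            ("C4'", "O4'", "C1'")]
    tors = [("C4'", "O4'", "C1'", "C2'"), ("O4'", "C1'", "C2'", "C3'"),
            ("C1'", "C2'", "C3'", "C4'"), ("C2'", "C3'", "C4'", "O4'"),
            ("C3'", "C4'", "O4'", "C1'")]
    blen = {bd: np.linalg.norm(cc[bd[0]] - cc[bd[1]]) for bd in bonds}
    bang = {an: angle(cc[an[0]], cc[an[1]], cc[an[2]]) for an in angs}
    nut = ring_torsion_targets(P, numax)

    def unpack(v):
        pos = {"C1'": np.zeros(3),
               "O4'": np.array([blen[("O4'", "C1'")], 0, 0]),
               "C4'": np.array([v[0], v[1], 0.0]),
               "C2'": v[2:5], "C3'": v[5:8]}
        return pos

    def resid(v):
        pos = unpack(v)
        r = []
        for bd in bonds:
            r.append(10 * (np.linalg.norm(pos[bd[0]] - pos[bd[1]])
                           - blen[bd]))
        for an in angs:
            r.append(0.2 * (angle(*[pos[a] for a in an]) - bang[an]))
        for k, tn in enumerate(tors):
            r.append(0.5 * (dihedral(*[pos[a] for a in tn]) - nut[k]))
        return r

    v0 = np.array([2.2, 1.2, -0.5, 1.3, 0.4, 0.9, 2.2, -0.2])
    sol = least_squares(resid, v0, xtol=1e-14, ftol=1e-14)
    pos = unpack(sol.x)
    got = [dihedral(*[pos[a] for a in tn]) for tn in tors]
    num = (got[4] + got[1]) - (got[3] + got[0])
    den = 2 * got[2] * (np.sin(np.radians(36)) + np.sin(np.radians(72)))
    got_P = np.degrees(np.arctan2(num, den)) % 360
    print(f"  ring chem={chem} target P={P} achieved P={got_P:.1f}")
    return pos


def subst_basis(C, R1, R2):
    u, v = unit(R1 - C), unit(R2 - C)
    b = -unit(u + v)
    n = unit(np.cross(u, v))
    return b, n, np.cross(b, n)


def measure_subst(cc, Cn, R1n, R2n, Xn):
    b, n, t = subst_basis(cc[Cn], cc[R1n], cc[R2n])
    d = cc[Xn] - cc[Cn]
    return np.array([d @ b, d @ n, d @ t])


def place_subst(pos, Cn, R1n, R2n, comp):
    b, n, t = subst_basis(pos[Cn], pos[R1n], pos[R2n])
    return pos[Cn] + comp[0] * b + comp[1] * n + comp[2] * t


def build_sugar(form):
    """Sugar + 5' phosphate + O3' in a local frame, plus the unit vector
    from C1' toward the glycosidic nitrogen."""
    chem = "ribo" if form == "A" else "deoxy"
    ref = ccd("A" if chem == "ribo" else "DA")
    P_pucker, numax = (18.0, 38.0) if form == "A" else (162.0, 37.0)
    pos = build_ring(P_pucker, numax, chem)
    # exocyclic substituents from CCD local descriptors
    pos["O3'"] = place_subst(pos, "C3'", "C2'", "C4'",
                             measure_subst(ref, "C3'", "C2'", "C4'", "O3'"))
    pos["C5'"] = place_subst(pos, "C4'", "C3'", "O4'",
                             measure_subst(ref, "C4'", "C3'", "O4'", "C5'"))
    if chem == "ribo":
        pos["O2'"] = place_subst(pos, "C2'", "C1'", "C3'",
                                 measure_subst(ref, "C2'", "C1'", "C3'",
                                               "O2'"))
    nvec = place_subst(pos, "C1'", "O4'", "C2'",
                       measure_subst(ref, "C1'", "O4'", "C2'", "N9"))
    u_n = unit(nvec - pos["C1'"])
    r_n = np.linalg.norm(ref["N9"] - ref["C1'"])
    return pos, u_n, r_n, ref


def finish_backbone(pos, ref, gamma, beta):
    out = dict(pos)
    out["O5'"] = nerf(out["C3'"], out["C4'"], out["C5'"],
                      np.linalg.norm(ref["C5'"] - ref["O5'"]),
                      angle(ref["C4'"], ref["C5'"], ref["O5'"]), gamma)
    out["P"] = nerf(out["C4'"], out["C5'"], out["O5'"],
                    np.linalg.norm(ref["O5'"] - ref["P"]),
                    angle(ref["C5'"], ref["O5'"], ref["P"]), beta)
    for opn in ("OP1", "OP2"):
        out[opn] = nerf(out["C5'"], out["O5'"], out["P"],
                        np.linalg.norm(ref["P"] - ref[opn]),
                        angle(ref["O5'"], ref["P"], ref[opn]),
                        dihedral(ref["C5'"], ref["O5'"], ref["P"],
                                 ref[opn]))
    return out


# -------------------------------------------------------- pair-frame solve

WC_HBONDS = {
    ("A", "U"): [("N6", "O4", 2.95), ("N1", "N3", 2.82)],
    ("A", "T"): [("N6", "O4", 2.95), ("N1", "N3", 2.82)],
    ("G", "C"): [("O6", "N4", 2.91), ("N1", "N3", 2.95), ("N2", "O2", 2.86)],
}

FORM = {
    "A": dict(twist=32.7, rise=2.81, chem="ribo",
              bases=["A", "G", "C", "U"], chi0=-158.0, gamma0=54.0,
              beta0=178.0, y0=-6.9, alpha0=-68.0),
    "B": dict(twist=36.0, rise=3.38, chem="deoxy",
              bases=["DA", "DG", "DC", "DT"], chi0=-102.0, gamma0=48.0,
              beta0=176.0, y0=-2.5, alpha0=-63.0),
}

COMP_RNA = {"A": "U", "U": "A", "G": "C", "C": "G"}
COMP_DNA = {"A": "T", "T": "A", "G": "C", "C": "G"}


def base_pose_left(b2d, lam, c1c1, y0, r_n):
    """Rigidly pose a 2D base (origin N, +x toward C1') in the pair plane:
    C1' at (-c1c1/2, y0) with the glycosidic bond at angle lam from +x."""
    d = np.array([np.cos(np.radians(lam)), np.sin(np.radians(lam))])
    c1 = np.array([-c1c1 / 2.0, y0])
    npos = c1 + r_n * d
    # base +x axis (N->C1') must map to -d
    ex = -d
    ey = np.array([-ex[1], ex[0]])
    return {n: npos + xy[0] * ex + xy[1] * ey for n, xy in b2d.items()}


def mirror_x(p2d):
    return {n: np.array([-xy[0], xy[1]]) for n, xy in p2d.items()}


def to3d(p2d):
    return {n: np.array([xy[0], xy[1], 0.0]) for n, xy in p2d.items()}


def orient_sugar(sugar, u_n, c1_target, d3, chi_target, chi_atoms,
                 n_pos, cref_pos):
    """Rigidly place the sugar: C1' at c1_target, C1'->N direction = d3,
    rotation about that axis chosen so chi hits its target."""
    # R0: take u_n to d3
    v = np.cross(u_n, d3)
    c = np.dot(u_n, d3)
    if np.linalg.norm(v) < 1e-12:
        R0 = np.eye(3)
    else:
        K = np.array([[0, -v[2], v[1]], [v[2], 0, -v[0]], [-v[1], v[0], 0]])
        R0 = np.eye(3) + K + K @ K * (1 / (1 + c))

    def placed(psi):
        R = rot_axis(d3, psi) @ R0
        return {n: c1_target + R @ (p - sugar["C1'"])
                for n, p in sugar.items()}

    def chi_of(psi):
        s = placed(psi)
        return dihedral(s[chi_atoms[0]], s[chi_atoms[1]], n_pos, cref_pos)

    # chi is linear in psi up to sign
    c0 = chi_of(0.0)
    c1 = chi_of(10.0)
    slope = ((c1 - c0 + 180) % 360) - 180
    psi = 10.0 * (((chi_target - c0 + 180) % 360) - 180) / slope
    got = chi_of(psi)
    assert abs(((got - chi_target + 180) % 360) - 180) < 1e-6, got
    return placed(psi)


def helix_op(p, twist, rise, k=1):
    R = rot_axis(np.array([0.0, 0, 1]), twist * k)
    return R @ p + np.array([0.0, 0, rise * k])


def ry180(p):
    return np.array([-p[0], p[1], -p[2]])


def assemble_form(form):
    cfg = FORM[form]
    sugar0, u_n, r_n, ref = build_sugar(form)
    b2d = {rn: flat_base(rn) for rn in cfg["bases"]}

    def build(vars):
        lam, c1c1, y0, chi, gamma, beta = vars
        res_tpl = {}
        for rn in cfg["bases"]:
            bl = base_letter(rn)
            bp = base_pose_left(b2d[rn], lam, c1c1, y0, r_n)
            b3 = to3d(bp)
            c1t = b3["C1'"]
            npos = b3[glyco_n(rn)]
            d3 = unit(npos - c1t)
            cref = b3["C4" if bl in "AG" else "C2"]
            sug = orient_sugar(sugar0, u_n, c1t, d3, chi,
                               ("O4'", "C1'"), npos, cref)
            sug = finish_backbone(sug, ref, gamma, beta)
            atoms = {n: b3[n] for n in base_atom_names(rn)}
            atoms.update({n: p for n, p in sug.items() if n != "C1'"})
            atoms["C1'"] = c1t
            res_tpl[rn] = atoms
        return res_tpl

    def residuals(vars):
        lam, c1c1, y0, chi, gamma, beta = vars
        tpl = build(vars)
        r = []
        # WC hydrogen bonds: left base vs mirror of complement
        comp_map = COMP_RNA if cfg["chem"] == "ribo" else COMP_DNA
        for rn in cfg["bases"]:
            bl = base_letter(rn)
            if bl not in ("A", "G"):
                continue
            comp = comp_map[bl]
            crn = [x for x in cfg["bases"] if base_letter(x) == comp][0]
            right = {n: ry180(p) for n, p in tpl[crn].items()}
            for d_at, a_at, tgt in WC_HBONDS[(bl, comp)]:
                r.append(2.0 * (np.linalg.norm(tpl[rn][d_at] - right[a_at])
                                - tgt))
        # B form: helix axis through the pair centers (mean base atoms of
        # the two strands), so stacked pair centers are 'rise' apart
        if form == "B":
            for rn in cfg["bases"]:
                comp = comp_map2 = (COMP_DNA if cfg["chem"] == "deoxy"
                                    else COMP_RNA)[base_letter(rn)]
                crn = [x for x in cfg["bases"]
                       if base_letter(x) == comp][0]
                right = {n: ry180(p) for n, p in tpl[crn].items()}
                pts = ([tpl[rn][n] for n in base_atom_names(rn)] +
                       [right[n] for n in base_atom_names(crn)])
                ctr = np.mean(pts, axis=0)
                r.append(4.0 * ctr[0])
                r.append(4.0 * ctr[1])
        # backbone closure O3'(i) -- P(i+1)
        tA = tpl[cfg["bases"][0]]
        pn = helix_op(tA["P"], cfg["twist"], cfg["rise"])
        r.append(10.0 * (np.linalg.norm(pn - tA["O3'"]) - 1.60))
        # soft torsion priors across the junction
        o3prev = helix_op(tA["O3'"], cfg["twist"], cfg["rise"], k=-1)
        alpha = dihedral(o3prev, tA["P"], tA["O5'"], tA["C5'"])
        zeta = dihedral(tA["C3'"], tA["O3'"], pn,
                        helix_op(tA["O5'"], cfg["twist"], cfg["rise"]))
        eps = dihedral(tA["C4'"], tA["C3'"], tA["O3'"], pn)
        r.append(0.05 * (((alpha - cfg["alpha0"] + 180) % 360) - 180))
        r.append(0.03 * (((zeta + 90 + 180) % 360) - 180))
        r.append(0.03 * (((eps + 155 + 180) % 360) - 180))
        # parameter priors
        wrap = lambda x: ((x + 180) % 360) - 180
        r.append(0.15 * (lam - 54.5))
        r.append(0.5 * (c1c1 - 10.4))
        r.append(0.10 * (y0 - cfg["y0"]))
        r.append(0.03 * wrap(chi - cfg["chi0"]))
        r.append(0.03 * wrap(gamma - cfg["gamma0"]))
        r.append(0.03 * wrap(beta - cfg["beta0"]))
        return r

    v0 = np.array([54.5, 10.4, cfg["y0"], cfg["chi0"], cfg["gamma0"],
                   cfg["beta0"]])
    lb = [45.0, 9.9, cfg["y0"] - 3.0, cfg["chi0"] - 45.0,
          cfg["gamma0"] - 45.0, cfg["beta0"] - 45.0]
    ub = [64.0, 10.9, cfg["y0"] + 3.0, cfg["chi0"] + 45.0,
          cfg["gamma0"] + 45.0, cfg["beta0"] + 45.0]
    sol = least_squares(residuals, v0, bounds=(lb, ub),
                        xtol=1e-12, ftol=1e-12)
    lam, c1c1, y0, chi, gamma, beta = sol.x
    tpl = build(sol.x)
    tA = tpl[cfg["bases"][0]]
    pn = helix_op(tA["P"], cfg["twist"], cfg["rise"])
    o3prev = helix_op(tA["O3'"], cfg["twist"], cfg["rise"], k=-1)
    closure = np.linalg.norm(pn - tA["O3'"])
    alpha = dihedral(o3prev, tA["P"], tA["O5'"], tA["C5'"])
    print(f"form {form}: lam={lam:.2f} c1c1={c1c1:.2f} y0={y0:.2f} "
          f"chi={chi:.1f} gamma={gamma:.1f} beta={beta:.1f}")
    print(f"  closure={closure:.3f} A  alpha={alpha:.1f}")
    return tpl


def write_form(form, tpl):
    cfg = FORM[form]
    path = f"{OUT}/synthetic_fiber_{form}.txt"
    with open(path, "w") as fh:
        fh.write("# Synthetic idealized fiber nucleotide templates, "
                 f"form {form} ({cfg['chem']}).\n")
        fh.write("# Constructed geometry (data-raw/make_templates.py); "
                 "not experimental coordinates.\n")
        fh.write(f"# twist {cfg['twist']} rise {cfg['rise']}\n")
        fh.write("resname atom element x y z\n")
        for rn, atoms in tpl.items():
            for n, p in atoms.items():
                fh.write(f"{rn} {n} {n[0]} "
                         f"{p[0]:.4f} {p[1]:.4f} {p[2]:.4f}\n")
    print("wrote", path)


# ------------------------------------------------------------ HG templates

HG_DEFS = {
    # name: (form, purine resname, partner resname, hbond list, c1c1)
    "AT": ("B", "DA", "DT", [("N7", "N3", 2.87), ("N6", "O4", 2.93)], 8.5),
    "AU": ("A", "A", "U", [("N7", "N3", 2.87), ("N6", "O4", 2.93)], 8.5),
    "GC": ("A", "G", "C", [("N7", "N3", 2.90), ("O6", "N4", 2.90)], 8.6),
    "GG": ("B", "DG", "DG", [("O6", "N1", 2.80), ("N7", "N2", 2.90)], 10.4),
}


def assemble_hg(name):
    form, prn, qrn, hbonds, c1c1_t = HG_DEFS[name]
    cfg = FORM[form]
    sugar0, u_n, r_n, ref = build_sugar(form)
    # partner: right-side residue exactly as in the WC frame of this form
    lam, c1c1_wc, y0 = 54.5, 10.4, cfg["y0"]
    q2d = flat_base(qrn)
    qpose = base_pose_left(q2d, lam, c1c1_wc, y0, r_n)
    q3 = {n: ry180(p) for n, p in to3d(qpose).items()}
    qc1 = q3["C1'"]
    qn = q3[glyco_n(qrn)]
    qd = unit(qn - qc1)
    qcref = q3["C2" if base_letter(qrn) not in "AG" else "C4"]
    # partner sugar: mirror of the left-template sugar orientation
    qsug = orient_sugar({n: ry180(p) for n, p in sugar0.items()},
                        ry180(u_n), qc1, qd, cfg["chi0"],
                        ("O4'", "C1'"), qn, qcref)
    qsug = {n: p for n, p in qsug.items()}

    # syn purine base: mirrored 2D layout (base flipped over), posed by
    # least squares on the hydrogen bonds and the C1'-C1' distance
    p2d = mirror_x(flat_base(prn))

    def pose(vars):
        tx, ty, th = vars
        R = np.array([[np.cos(np.radians(th)), -np.sin(np.radians(th))],
                      [np.sin(np.radians(th)), np.cos(np.radians(th))]])
        return {n: np.array([tx, ty]) + R @ xy for n, xy in p2d.items()}

    def resid(vars):
        pp = pose(vars)
        r = []
        for d_at, a_at, tgt in hbonds:
            r.append(np.linalg.norm(np.append(pp[d_at], 0.0) - q3[a_at])
                     - tgt)
        r.append(0.7 * (np.linalg.norm(np.append(pp["C1'"], 0.0) - qc1)
                        - c1c1_t))
        return r

    sol = least_squares(resid, np.array([-4.0, y0 + 1.0, 160.0]))
    pp = pose(sol.x)
    p3 = to3d(pp)
    pc1 = p3["C1'"]
    pn = p3[glyco_n(prn)]
    pd = unit(pn - pc1)
    pcref = p3["C4"]
    psug = orient_sugar(sugar0, u_n, pc1, pd, 60.0, ("O4'", "C1'"),
                        pn, pcref)
    print(f"HG {name}: hbond residuals "
          f"{[round(float(x), 3) for x in resid(sol.x)]}")

    def res_atoms(rn, b3, sug):
        atoms = {n: b3[n] for n in base_atom_names(rn)}
        atoms.update({n: p for n, p in sug.items() if n != "C1'"})
        atoms["C1'"] = b3["C1'"]
        return atoms

    path = f"{OUT}/synthetic_hg_{name}_{form}.txt"
    with open(path, "w") as fh:
        fh.write(f"# Synthetic Hoogsteen pair template {prn}(syn)-{qrn}, "
                 f"form {form} sugars.\n")
        fh.write("# Constructed geometry (data-raw/make_templates.py); "
                 "not experimental coordinates.\n")
        fh.write("chain resno resname atom element x y z\n")
        for ch, rn, atoms in (("A", 1, res_atoms(prn, p3, psug)),
                              ("B", 1, res_atoms(qrn, q3, qsug))):
            for n, p in atoms.items():
                fh.write(f"{ch} {rn} {HG_DEFS[name][1 if ch == 'A' else 2]}"
                         f" {n} {n[0]} {p[0]:.4f} {p[1]:.4f} {p[2]:.4f}\n")
    print("wrote", path)


if __name__ == "__main__":
    import os
    os.makedirs(OUT, exist_ok=True)
    for form in ("A", "B"):
        tpl = assemble_form(form)
        write_form(form, tpl)
    for name in HG_DEFS:
        assemble_hg(name)
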