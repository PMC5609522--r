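>PIP2_anchor_synthetic
MSKEEDVRGEYGHQSTDKGEILVFILVFLIVFLIVLFIVLFIVLIGDRSHGGEPKQDSTAGHELIVFLIVFILVFFFIVL
IVFLIVFLTSFKEGDSNPAGGSTLETSGKEVLIFVLIFLVIFLIVFLVIFLIVFLGDSLEKHGQSTDPEHKGSILVFILF
VLIVFLIVFILVFLIVLFGERSGDGKHSTEFLIVFLIVFLIVHLIVFLIVFLIVFGDSNPAGTGRSGSQSAGEGTKDNEH
STGKEVLIFVLIFVLIFLIVFLIVFLIVFIGSDFEWKSTEGDHKETSG
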