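<?xml version="1.0" encoding="UTF-8"?>
<!-- TMA XML dialect accepted by convert_tma_xml(): tma > block > {slide, core};
     cores under a slide are cores-on-slide, cores under a block are
     cores-in-block. Unknown simple child elements of tma/block/slide/core are
     carried along as datatype-property candidates. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:element name="tma">
    <xs:complexType>
      <xs:sequence>
        <xs:any processContents="lax" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="identifier" type="xs:string" use="required"/>
      <xs:attribute name="title" type="xs:string"/>
      <xs:attribute name="creator" type="xs:string"/>
      <xs:attribute name="repository" type="xs:string"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="block">
    <xs:complexType>
      <xs:sequence>
        <xs:any processContents="lax" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="identifier" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="slide">
    <xs:complexType>
      <xs:sequence>
        <xs:any processContents="lax" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="identifier" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

  <xs:element name="core">
    <xs:complexType>
      <xs:sequence>
        <xs:any processContents="lax" minOccurs="0" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="identifier" type="xs:string" use="required"/>
      <xs:attribute name="location" type="xs:string"/>
      <xs:attribute name="drill_site" type="xs:string"/>
      <xs:attribute name="donor_block" type="xs:string"/>
      <xs:attribute name="diagnosis_term" type="xs:string"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
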